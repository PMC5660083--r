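#' Site-by-taxon abundance table
#'
#' The central community container: a numeric matrix of site-level mean
#' abundances (sites as rows, taxa as columns) plus a guild label for every
#' taxon. Abundances are unitless relative cover values; they are never
#' negative.
#'
#' @param values numeric matrix, sites as rows and taxa as columns, with
#'   unique row and column names.
#' @param guild named character vector mapping every taxon to one of
#'   `"vascular"`, `"bryophyte"` or `"other"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, guild) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs site row names and taxon column names")
  if (anyDuplicated(rownames(values))) stop("site ids must be unique")
  if (anyDuplicated(colnames(values))) stop("taxon ids must be unique")
  if (any(!is.finite(values))) stop("abundance values must be finite")
  if (any(values < 0)) stop("abundance values must be non-negative")
  guild <- unlist(guild)
  missing <- setdiff(colnames(values), names(guild))
  if (length(missing))
    stop("guild undefined for taxa: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(guild), c("vascular", "bryophyte", "other"))
  if (length(bad))
    stop("unknown guild label(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, guild = guild[colnames(values)]),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "sites x", ncol(x$values), "taxa\n")
  cat("guilds:", paste(sprintf("%s=%d", names(table(x$guild)),
                               table(x$guild)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname abundance_table
#' @param ab an `abundance_table`.
#' @export
sites <- function(ab) rownames(ab$values)

#' @rdname abundance_table
#' @export
taxa <- function(ab) colnames(ab$values)

#' Restrict an abundance table to one guild
#'
#' @param ab an `abundance_table`.
#' @param guild `"vascular"`, `"bryophyte"` or `"other"`.
#' @param drop_empty_taxa drop taxa with zero total abundance after
#'   subsetting (default `FALSE`).
#' @return An `abundance_table` containing only taxa of the requested guild.
#' @export
subset_guild <- function(ab, guild, drop_empty_taxa = FALSE) {
  keep <- names(ab$guild)[ab$guild == guild]
  if (!length(keep)) stop("no taxa of guild '", guild, "'")
  v <- ab$values[, keep, drop = FALSE]
  if (drop_empty_taxa) v <- v[, colSums(v) > 0, drop = FALSE]
  abundance_table(v, ab$guild[colnames(v)])
}

# required environmental columns, in canonical order
.env_columns <- c("MAT", "TS", "MAP", "PS", "PTwarm",
                  "SOx", "NHx", "NOy", "lat", "lon")

#' Site-by-environment table
#'
#' Validates and classes a data frame of per-site environmental predictors:
#' mean annual temperature (`MAT`, degC), temperature seasonality (`TS`,
#' degC), mean annual precipitation (`MAP`, mm), precipitation seasonality
#' (`PS`), warm-quarter moisture index (`PTwarm`, mm/degC), sulphur and
#' nitrogen deposition (`SOx`, `NHx`, `NOy`, mg m-2 yr-1) and coordinates
#' (`lat`, `lon`, degrees).
#'
#' @param df data frame with a `site` column and the columns above.
#' @return An object of classes `env_table` and `data.frame`.
#' @export
env_table <- function(df) {
  df <- as.data.frame(df)
  if (!"site" %in% names(df)) stop("env table needs a 'site' column")
  missing <- setdiff(.env_columns, names(df))
  if (length(missing))
    stop("env table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$site)) stop("site ids must be unique")
  num <- df[, .env_columns]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(num))))
    stop("environmental columns must be numeric with no missing cells")
  df <- df[, c("site", .env_columns)]
  df$site <- as.character(df$site)
  class(df) <- c("env_table", "data.frame")
  df
}

#' Taxon-by-trait table
#'
#' Quantitative traits are numeric columns; categorical traits (life form
#' and the like) are factor columns. Character columns are promoted to
#' factors. Every taxon of the paired guild must have a complete trait row.
#'
#' @param df data frame of trait values with taxon ids as row names (or a
#'   `taxon` column, which is moved to row names).
#' @return An object of classes `trait_table` and `data.frame`.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df)
  if ("taxon" %in% names(df)) {
    rownames(df) <- df$taxon
    df$taxon <- NULL
  }
  if (is.null(rownames(df)) || anyDuplicated(rownames(df)))
    stop("trait table needs unique taxon row names")
  # factors normalized to alphabetical levels so CSV round-trips are exact
  for (j in seq_along(df))
    if (is.character(df[[j]]) || is.factor(df[[j]]))
      df[[j]] <- factor(as.character(df[[j]]))
  quant <- vapply(df, is.numeric, logical(1))
  if (any(!is.finite(as.matrix(df[, quant, drop = FALSE]))))
    stop("quantitative trait values must be finite (no missing cells)")
  if (any(vapply(df, anyNA, logical(1))))
    stop("trait table must have no missing values")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Check cross-table id alignment
#'
#' Verifies that an abundance, environment and (per-guild) trait tables
#' refer to the same sites and taxa: every site in the abundance table has
#' an environment row, and every taxon of a trait table's guild has a trait
#' row.
#'
#' @param ab an `abundance_table`.
#' @param env an `env_table` (optional).
#' @param traits a `trait_table` (optional).
#' @param guild guild covered by `traits`.
#' @return `TRUE` invisibly; stops with an informative message otherwise.
#' @export
validate_alignment <- function(ab, env = NULL, traits = NULL, guild = NULL) {
  if (!is.null(env)) {
    miss <- setdiff(sites(ab), env$site)
    if (length(miss))
      stop("sites missing from env table: ", paste(miss, collapse = ", "))
  }
  if (!is.null(traits)) {
    if (is.null(guild)) stop("guild must be given with a trait table")
    want <- names(ab$guild)[ab$guild == guild]
    miss <- setdiff(want, rownames(traits))
    if (length(miss))
      stop("taxa of guild '", guild, "' missing from trait table: ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

# full-precision numeric formatting so CSV round-trips are bitwise exact
.fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[x == round(x) & abs(x) < 2^52] <-
    sprintf("%.0f", x[x == round(x) & abs(x) < 2^52])
  out
}

.write_csv <- function(df, file) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  utils::write.table(df, file, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Write / read an abundance table as CSV
#'
#' The value matrix is written sites-as-rows with an `site` id column; guild
#' labels go to a separate two-column CSV (`taxon,guild`). Reading the pair
#' back reproduces the table exactly (values to full double precision,
#' row/column order preserved).
#'
#' @param ab an `abundance_table`.
#' @param file path of the values CSV.
#' @param guild_file path of the guild CSV.
#' @return `write_abundance` returns `file` invisibly; `read_abundance`
#'   returns an `abundance_table`.
#' @export
write_abundance <- function(ab, file, guild_file) {
  df <- data.frame(site = sites(ab), as.data.frame(ab$values),
                   check.names = FALSE)
  .write_csv(df, file)
  .write_csv(data.frame(taxon = taxa(ab), guild = unname(ab$guild)),
             guild_file)
  invisible(file)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(file, guild_file) {
  df <- utils::read.csv(file, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  g <- utils::read.csv(guild_file, fileEncoding = "UTF-8")
  abundance_table(m, stats::setNames(g$guild, g$taxon))
}

#' Write / read an environment table as CSV
#'
#' @param env an `env_table`.
#' @param file path of the CSV.
#' @return `write_env` returns `file` invisibly; `read_env` an `env_table`.
#' @export
write_env <- function(env, file) {
  .write_csv(as.data.frame(env), file)
  invisible(file)
}

#' @rdname write_env
#' @export
read_env <- function(file) {
  env_table(utils::read.csv(file, fileEncoding = "UTF-8"))
}

#' Write / read a trait table as CSV
#'
#' Categorical traits are stored as plain strings and restored as factors.
#'
#' @param traits a `trait_table`.
#' @param file path of the CSV.
#' @return `write_traits` returns `file` invisibly; `read_traits` a
#'   `trait_table`.
#' @export
write_traits <- function(traits, file) {
  df <- data.frame(taxon = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  .write_csv(df, file)
  invisible(file)
}

#' @rdname write_traits
#' @export
read_traits <- function(file) {
  trait_table(utils::read.csv(file, check.names = FALSE,
                              fileEncoding = "UTF-8"))
}
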