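GENERATIONS <- c("P1", "P2", "F1", "F2")

#' Long-format multi-generation phenotype tables
#'
#' The universal pipeline input: one record per plant and trait, with columns
#' `population`, `environment`, `generation` (one of P1, P2, F1, F2),
#' `individual`, `trait`, `value`. Missing values are absent records, never
#' sentinels.
#'
#' @param records a data frame with the six columns above (extra columns are
#'   dropped with a warning).
#' @return a validated data frame of class `"phenotype_table"`.
#' @export
phenotype_table <- function(records) {
  required <- c("population", "environment", "generation", "individual",
                "trait", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(records), required)
  if (length(extra)) {
    warning("dropping unused column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$generation <- normalize_generation(records$generation)
  if (!is.numeric(records$value)) {
    suppressWarnings(val <- as.numeric(records$value))
    bad <- which(is.na(val) & !is.na(records$value))
    if (length(bad)) {
      stop(sprintf("non-numeric trait value in row %d: '%s'",
                   bad[1L], records$value[bad[1L]]), call. = FALSE)
    }
    records$value <- val
  }
  if (any(!is.finite(records$value))) {
    stop(sprintf("non-finite trait value in row %d",
                 which(!is.finite(records$value))[1L]), call. = FALSE)
  }
  for (col in c("population", "environment", "individual", "trait")) {
    records[[col]] <- as.character(records[[col]])
  }
  rownames(records) <- NULL
  class(records) <- c("phenotype_table", "data.frame")
  records
}

normalize_generation <- function(x) {
  x_raw <- as.character(x)
  x_up <- toupper(trimws(x_raw))
  bad <- which(!(x_up %in% GENERATIONS))
  if (length(bad)) {
    stop(sprintf("unknown generation label in row %d: '%s' (allowed: %s)",
                 bad[1L], x_raw[bad[1L]], paste(GENERATIONS, collapse = ", ")),
         call. = FALSE)
  }
  factor(x_up, levels = GENERATIONS)
}

#' Read a phenotype table from delimited text
#'
#' @param path CSV (or other delimited) file with a header row.
#' @param schema optional named character vector mapping the standard column
#'   names (`population`, `environment`, `generation`, `individual`, `trait`,
#'   `value`) to the column names used in the file.
#' @param sep field separator, comma by default.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema))) stop("schema must be named", call. = FALSE)
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent)) {
      stop("schema names column(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (std in names(schema)) names(raw)[names(raw) == schema[[std]]] <- std
  }
  phenotype_table(raw)
}

#' Write a phenotype table to CSV
#'
#' @param data a [phenotype_table()].
#' @param path output file path.
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(inherits(data, "phenotype_table"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a wide one-row-per-plant table to long format
#'
#' Convenience converter for field sheets where each trait is a column.
#'
#' @param data data frame with `population`, `environment`, `generation`,
#'   `individual` columns plus one column per trait.
#' @param traits character vector of trait column names; defaults to every
#'   non-id column.
#' @return a [phenotype_table()]; rows with missing trait values are dropped
#'   (missing values are absent records).
#' @export
pivot_phenotypes <- function(data, traits = NULL) {
  ids <- c("population", "environment", "generation", "individual")
  missing_cols <- setdiff(ids, names(data))
  if (length(missing_cols)) {
    stop("missing id column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) traits <- setdiff(names(data), ids)
  if (!length(traits)) stop("no trait columns", call. = FALSE)
  long <- do.call(rbind, lapply(traits, function(tr) {
    cbind(data[ids], trait = tr, value = data[[tr]])
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  phenotype_table(long)
}

#' Split a phenotype table into per-generation value vectors
#'
#' @param data a [phenotype_table()].
#' @param trait,population,environment optional selectors; each defaults to
#'   the single level present (ambiguity is an error).
#' @return named list of numeric vectors `P1`, `P2`, `F1`, `F2` (generations
#'   with no records are absent).
#' @export
generation_values <- function(data, trait = NULL, population = NULL,
                              environment = NULL) {
  stopifnot(inherits(data, "phenotype_table"))
  pick <- function(col, chosen) {
    levels_present <- unique(data[[col]])
    if (is.null(chosen)) {
      if (length(levels_present) > 1L) {
        stop(sprintf("multiple %ss present (%s); select one", col,
                     paste(levels_present, collapse = ", ")), call. = FALSE)
      }
      levels_present
    } else {
      if (!chosen %in% levels_present) {
        stop(sprintf("%s '%s' not present", col, chosen), call. = FALSE)
      }
      chosen
    }
  }
  keep <- data$trait == pick("trait", trait) &
    data$population == pick("population", population) &
    data$environment == pick("environment", environment)
  sub <- data[keep, , drop = FALSE]
  out <- lapply(split(sub$value, sub$generation, drop = FALSE), as.numeric)
  out[vapply(out, length, 0L) > 0L]
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "<phenotype_table> %d records; %d trait(s); generations: %s\n",
    nrow(x), length(unique(x$trait)),
    paste(sprintf("%s=%d", levels(x$generation), table(x$generation)),
          collapse = ", ")))
  NextMethod()
}
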