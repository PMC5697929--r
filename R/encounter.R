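#' Encounter-history object
#'
#' Bundles a binary individuals x occasions detection matrix with its season
#' calendar. Rows are named by individual id; the first detection column of
#' each row is recorded as `first_occasion` (the likelihood conditions on it).
#'
#' @param mat 0/1 matrix, individuals in rows, occasions in columns, with
#'   rownames giving individual ids. A zero-row matrix is valid.
#' @param calendar A `season_calendar` with one row per matrix column.
#' @return An object of class `encounter_history`.
#' @export
encounter_history <- function(mat, calendar) {
  stopifnot(inherits(calendar, "season_calendar"))
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (ncol(mat) != nrow(calendar))
    stop("matrix has ", ncol(mat), " columns but calendar has ",
         nrow(calendar), " occasions")
  if (nrow(mat) > 0L) {
    if (is.null(rownames(mat)))
      rownames(mat) <- as.character(seq_len(nrow(mat)))
    if (!all(mat %in% c(0L, 1L))) stop("matrix entries must be 0 or 1")
    rs <- rowSums(mat)
    if (any(rs == 0L))
      stop("every individual needs at least one detection; offending ids: ",
           paste(utils::head(rownames(mat)[rs == 0L], 5L), collapse = ", "))
    first <- apply(mat == 1L, 1L, which.max)
  } else {
    first <- integer(0)
  }
  structure(list(matrix = mat, calendar = calendar,
                 first_occasion = as.integer(first)),
            class = "encounter_history")
}

#' @export
print.encounter_history <- function(x, ...) {
  cat("Encounter history:", nrow(x$matrix), "individuals x",
      ncol(x$matrix), "occasions (",
      sum(x$calendar$type == "summer"), "summers,",
      sum(x$calendar$type == "winter"), "winters )\n")
  invisible(x)
}

#' @export
dim.encounter_history <- function(x) dim(x$matrix)

#' Build an encounter matrix from dated detection records
#'
#' Collapses a table of dated detections into the seasonal 0/1 encounter
#' matrix: a cell is 1 iff the individual has at least one `detection` record
#' inside that occasion's window. Non-detection events (e.g. nocturnal
#' departures) never produce a 1. Records dated outside the calendar are
#' dropped with a warning; the drop count is attached as attribute
#' `"n_dropped"`.
#'
#' @param records Data frame with columns `id`, `date`, `event`.
#' @param calendar A `season_calendar`.
#' @param ids Individuals to include (matrix row order). Defaults to all ids
#'   with at least one in-range detection, sorted.
#' @return An `encounter_history`.
#' @export
build_encounter_matrix <- function(records, calendar, ids = NULL) {
  stopifnot(all(c("id", "date", "event") %in% names(records)))
  det <- records[records$event == "detection", , drop = FALSE]
  occ <- occasion_of_date(calendar, det$date)
  n_dropped <- sum(is.na(occ) & nrow(det) > 0L)
  if (n_dropped > 0L)
    warning(n_dropped, " detection(s) outside the calendar range dropped")
  det <- det[!is.na(occ), , drop = FALSE]
  occ <- occ[!is.na(occ)]
  if (is.null(ids)) {
    ids <- sort(unique(as.character(det$id)))
  } else {
    ids <- as.character(ids)
    missing <- setdiff(ids, unique(as.character(det$id)))
    if (length(missing) > 0L)
      stop("no in-range detections for requested id(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  mat <- matrix(0L, nrow = length(ids), ncol = nrow(calendar),
                dimnames = list(ids, calendar$label))
  keep <- as.character(det$id) %in% ids
  if (any(keep))
    mat[cbind(match(as.character(det$id)[keep], ids), occ[keep])] <- 1L
  eh <- encounter_history(mat, calendar)
  attr(eh, "n_dropped") <- n_dropped
  eh
}

#' Read/write encounter histories with covariates as CSV
#'
#' The CSV dialect is `id,sex,age,strategy,first_occasion,o1..oT`, one row
#' per individual; the calendar travels separately
#' (see [write_season_calendar()]).
#'
#' @param history An `encounter_history`.
#' @param covariates Covariate data frame with columns `id`, `sex`, `age`,
#'   `strategy` (row order matching the matrix).
#' @param path File path.
#' @param calendar Calendar to attach on read.
#' @return `read_encounter_csv` returns `list(history, covariates)`.
#' @export
write_encounter_csv <- function(history, covariates, path) {
  stopifnot(inherits(history, "encounter_history"))
  m <- history$matrix
  stopifnot(identical(as.character(covariates$id), rownames(m)))
  occ <- as.data.frame(m)
  names(occ) <- paste0("o", seq_len(ncol(m)))
  out <- cbind(covariates[, c("id", "sex", "age", "strategy")],
               first_occasion = history$first_occasion, occ)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encounter_csv
#' @export
read_encounter_csv <- function(path, calendar) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  occ_cols <- grep("^o[0-9]+$", names(d), value = TRUE)
  occ_cols <- occ_cols[order(as.integer(sub("^o", "", occ_cols)))]
  mat <- as.matrix(d[, occ_cols, drop = FALSE])
  dimnames(mat) <- list(as.character(d$id), calendar$label)
  cov <- d[, c("id", "sex", "age", "strategy", "first_occasion"),
           drop = FALSE]
  cov$id <- as.character(cov$id)
  list(history = encounter_history(mat, calendar), covariates = cov)
}
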