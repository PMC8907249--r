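#' Discrete competing-risks dataset
#'
#' One record per individual: an observed interval index
#' \eqn{\tilde T_i \in \{1, \ldots, k\}}, a status code
#' \eqn{\Delta_i \epsilon_i \in \{0, 1, \ldots, J\}} (0 = censored, 1 = event
#' of interest, 2 or more = competing event), and a numeric covariate vector.
#'
#' @param time Integer vector of observed interval indices, each in `1:k`.
#' @param status Integer vector of status codes (0 = censored, 1 = event of
#'   interest, >= 2 = competing event).
#' @param x Numeric covariate matrix (or data frame coercible to one), one
#'   row per individual. Categorical predictors must be numerically encoded
#'   by the caller.
#' @param grid A [time_grid], or `NULL` to build one from `k`.
#' @param k Number of intervals; defaults to `max(time)` when no grid given.
#' @param J Number of event types; defaults to the maximum observed status
#'   (at least 1).
#' @return An object of class `cr_dataset` with fields `time`, `status`,
#'   `x`, `grid`, `J`.
#' @export
cr_dataset <- function(time, status, x, grid = NULL, k = NULL, J = NULL) {
  time <- as.integer(time)
  status <- as.integer(status)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(time)
  if (length(status) != n || nrow(x) != n)
    stop("'time', 'status' and 'x' must describe the same individuals")
  if (n == 0L) stop("empty dataset")
  if (anyNA(time) || anyNA(status) || anyNA(x))
    stop("missing values are not allowed")
  if (is.null(grid)) {
    if (is.null(k)) k <- max(time)
    grid <- time_grid(k)
  }
  if (any(time < 1L) || any(time > grid$k))
    stop("'time' must lie in 1..k (1-based interval indices)")
  if (any(status < 0L))
    stop("'status' must be a non-negative integer code")
  if (is.null(J)) J <- max(1L, max(status))
  if (max(status) > J) stop("status code exceeds J = ", J)
  if (all(status == 0L))
    warning("all individuals are censored; J set to ", J)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(time = time, status = status, x = x,
                 grid = grid, J = as.integer(J)),
            class = "cr_dataset")
}

#' Single-event survival dataset
#'
#' Output format of the imputation step: one record per individual with a
#' time index in `1:k`, a binary event indicator, and covariates. Any
#' single-event discrete-time learner can consume it.
#'
#' @param time Integer vector of interval indices in `1:k`.
#' @param event Binary (0/1) event indicator.
#' @param x Numeric covariate matrix.
#' @param grid A [time_grid], or `NULL` to build one from `max(time)`.
#' @return An object of class `se_dataset`.
#' @export
se_dataset <- function(time, event, x, grid = NULL) {
  time <- as.integer(time)
  event <- as.integer(event)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(time)
  if (length(event) != n || nrow(x) != n)
    stop("'time', 'event' and 'x' must describe the same individuals")
  if (anyNA(time) || anyNA(event) || anyNA(x))
    stop("missing values are not allowed")
  if (!all(event %in% c(0L, 1L))) stop("'event' must be 0 or 1")
  if (is.null(grid)) grid <- time_grid(max(time))
  if (any(time < 1L) || any(time > grid$k))
    stop("'time' must lie in 1..k")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(time = time, event = event, x = x, grid = grid),
            class = "se_dataset")
}

#' @export
print.cr_dataset <- function(x, ...) {
  cat("Discrete competing-risks dataset: n =", length(x$time),
      ", k =", x$grid$k, ", J =", x$J,
      ", p =", ncol(x$x), "\n")
  tab <- table(factor(x$status, levels = 0:x$J))
  cat("  status counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.se_dataset <- function(x, ...) {
  cat("Single-event discrete survival dataset: n =", length(x$time),
      ", k =", x$grid$k, ", p =", ncol(x$x), "\n")
  cat("  events:", sum(x$event), " censored:", sum(1L - x$event), "\n")
  invisible(x)
}

#' @export
as.data.frame.cr_dataset <- function(x, ...) {
  data.frame(time = x$time, status = x$status, x$x, check.names = FALSE)
}

#' @export
as.data.frame.se_dataset <- function(x, ...) {
  data.frame(time = x$time, event = x$event, x$x, check.names = FALSE)
}

# subset rows, keeping grid and J
cr_subset <- function(data, i) {
  structure(list(time = data$time[i], status = data$status[i],
                 x = data$x[i, , drop = FALSE],
                 grid = data$grid, J = data$J),
            class = "cr_dataset")
}

#' Read a delimited survival table
#'
#' Reads a delimited text file (comma default, tab accepted) with a header
#' into a [cr_dataset]. Required columns are an integer-valued time column
#' (1-based interval indices) and a non-negative integer status column; all
#' remaining columns are treated as numeric covariates unless
#' `covariate_cols` is given. Rows with missing values are rejected:
#' discarding incomplete records is the caller's responsibility.
#'
#' @param path Path to the file.
#' @param time_col,status_col Column names for time and status.
#' @param covariate_cols Optional character vector naming the covariate
#'   columns; default: every other column.
#' @param sep Field separator; `NULL` auto-detects comma versus tab from the
#'   header line.
#' @param k Number of grid intervals; defaults to the maximum observed time.
#' @return A [cr_dataset] with `J` equal to the maximum observed status.
#' @export
read_survival_table <- function(path, time_col = "time", status_col = "status",
                                covariate_cols = NULL, sep = NULL, k = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  for (col in c(time_col, status_col))
    if (!col %in% names(df))
      stop("configuration error: required column '", col, "' not found")
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(time_col, status_col))
  missing_cov <- setdiff(covariate_cols, names(df))
  if (length(missing_cov))
    stop("configuration error: covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "))
  na_row <- which(!stats::complete.cases(df[c(time_col, status_col, covariate_cols)]))
  if (length(na_row))
    stop("data error: missing value(s) in row(s) ",
         paste(utils::head(na_row, 5L), collapse = ", "))
  tm <- df[[time_col]]
  if (!is.numeric(tm) || any(tm != round(tm)))
    stop("format error: time column must be integer-valued")
  if (any(tm < 1))
    stop("format error: time indices must be >= 1 (1-based intervals)")
  st <- df[[status_col]]
  if (!is.numeric(st) || any(st != round(st)) || any(st < 0))
    stop("format error: status column must contain non-negative integers")
  xm <- df[covariate_cols]
  if (!all(vapply(xm, is.numeric, logical(1L))))
    stop("format error: covariate columns must be numeric ",
         "(encode categorical predictors before reading)")
  cr_dataset(as.integer(tm), as.integer(st), as.matrix(xm), k = k)
}

#' Write a survival dataset to a delimited table
#'
#' Serializes a [cr_dataset] or [se_dataset] with a header in a stable
#' column order (`time`, `status` or `event`, then covariates), so that
#' [read_survival_table()] round-trips it exactly.
#'
#' @param data A `cr_dataset` or `se_dataset`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path, sep = ",") {
  df <- as.data.frame(data)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Partitions a competing-risks dataset into three subsets whose status
#' composition (censored, event of interest, each competing event) matches
#' the requested proportions as closely as integer allocation permits.
#' Within each status category individuals are shuffled and allocated by
#' largest-remainder rounding, so the three subsets are disjoint and their
#' union is the input.
#'
#' @param data A [cr_dataset].
#' @param fractions Three positive proportions summing to 1
#'   (train, validation, test).
#' @param seed Optional integer seed; the split is deterministic given it.
#' @return A list with elements `train`, `validation`, `test`.
#' @export
stratified_split <- function(data, fractions = c(1 / 2, 1 / 6, 1 / 3),
                             seed = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be three positive proportions summing to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$time)
  assign_split <- integer(n)
  for (s in sort(unique(data$status))) {
    idx <- which(data$status == s)
    m <- length(idx)
    if (m < 3L)
      warning("status category ", s, " has only ", m,
              " member(s); best-effort allocation")
    idx <- idx[sample.int(m)]
    # largest-remainder allocation within the category
    raw <- fractions * m
    sizes <- floor(raw)
    rem <- m - sum(sizes)
    if (rem > 0) {
      extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    grp <- rep.int(1:3, sizes)
    assign_split[idx] <- grp
  }
  list(train = cr_subset(data, assign_split == 1L),
       validation = cr_subset(data, assign_split == 2L),
       test = cr_subset(data, assign_split == 3L))
}
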