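# Session time-series containers, band-pass filtering, scaling, windowing
# and chronological splitting.

#' Construct a session time series
#'
#' A session is one region-by-time signal matrix (e.g. parcellated BOLD
#' activity) with a fixed sampling interval. Rows must follow the same region
#' ordering as the adjacency matrices used downstream.
#'
#' @param values numeric matrix, regions in rows, time points in columns
#' @param sampling_interval seconds per time step (fMRI TR); default 0.72
#' @param session_id character label for the session
#' @return an object of class `session_ts`
#' @export
session_ts <- function(values, sampling_interval = 0.72,
                       session_id = "session") {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("a session needs at least one region and two time points")
  if (anyNA(values) || any(!is.finite(values)))
    stop("session values must be finite and non-missing")
  structure(
    list(values = values, sampling_interval = sampling_interval,
         session_id = session_id),
    class = "session_ts")
}

#' @export
print.session_ts <- function(x, ...) {
  cat(sprintf("<session_ts '%s': %d regions x %d time points, dt = %g s>\n",
              x$session_id, nrow(x$values), ncol(x$values),
              x$sampling_interval))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every region's series with the same order-5 Butterworth band-pass,
#' applied forward and backward (`signal::filtfilt`) so the output has no
#' phase shift. The 0.04-0.07 Hz band is the conventional choice for
#' resting-state BOLD at TR = 0.72 s.
#'
#' @param ts a [session_ts()]
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * sampling_interval)`
#' @param order Butterworth order (default 5)
#' @return a filtered `session_ts` of the same shape
#' @export
bandpass_filter <- function(ts, low_hz = 0.04, high_hz = 0.07, order = 5L) {
  stopifnot(inherits(ts, "session_ts"))
  nyq <- 1 / (2 * ts$sampling_interval)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("invalid band: need 0 < low < high < Nyquist (%.4g Hz)", nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(ts$values, 1L, function(row) signal::filtfilt(bf, row)))
  if (nrow(ts$values) == 1L) out <- matrix(out, 1L)
  dimnames(out) <- dimnames(ts$values)
  session_ts(out, ts$sampling_interval, ts$session_id)
}

#' Scale session signals
#'
#' Two modes are supported. `"minmax01"` linearly maps each session onto
#' \[0, 1\] using the session-wide minimum and maximum (the convention used
#' before model training). `"zscore"` removes, per region, the mean and
#' standard deviation pooled over all supplied sessions (the convention used
#' when reporting scale-free evaluation errors).
#'
#' @param x a `session_ts` or a list of them
#' @param mode `"minmax01"` or `"zscore"`
#' @return list with `data` (same structure as `x`, scaled) and `params`
#'   (a `scaling_params` object that [unscale_signals()] inverts)
#' @export
scale_signals <- function(x, mode = c("minmax01", "zscore")) {
  mode <- match.arg(mode)
  single <- inherits(x, "session_ts")
  sessions <- if (single) list(x) else x
  stopifnot(all(vapply(sessions, inherits, logical(1), "session_ts")))
  if (mode == "minmax01") {
    params <- lapply(sessions, function(s) {
      lo <- min(s$values); hi <- max(s$values)
      if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
        stop(sprintf("session '%s' is constant; minmax01 scaling is degenerate",
                     s$session_id))
      c(lo = lo, hi = hi)
    })
    names(params) <- vapply(sessions, `[[`, character(1), "session_id")
    scaled <- mapply(function(s, p) {
      session_ts((s$values - p["lo"]) / (p["hi"] - p["lo"]),
                 s$sampling_interval, s$session_id)
    }, sessions, params, SIMPLIFY = FALSE)
  } else {
    all_vals <- do.call(cbind, lapply(sessions, `[[`, "values"))
    mu <- rowMeans(all_vals)
    sdv <- apply(all_vals, 1L, stats::sd)
    if (any(sdv == 0))
      stop("constant region series; zscore scaling is degenerate")
    params <- list(mean = mu, sd = sdv)
    scaled <- lapply(sessions, function(s) {
      session_ts((s$values - mu) / sdv, s$sampling_interval, s$session_id)
    })
  }
  out <- structure(list(mode = mode, stats = params),
                   class = "scaling_params")
  list(data = if (single) scaled[[1L]] else scaled, params = out)
}

#' Invert a scaling transform
#' @param x scaled `session_ts`, list of them, or a bare matrix (interpreted
#'   with the stats of `session` for zscore, or of the named session for
#'   minmax01)
#' @param params the `scaling_params` returned by [scale_signals()]
#' @param session session id selecting minmax statistics for bare matrices
#' @return data on the original scale
#' @export
unscale_signals <- function(x, params, session = NULL) {
  stopifnot(inherits(params, "scaling_params"))
  inv_mat <- function(m, sid) {
    if (params$mode == "minmax01") {
      p <- params$stats[[sid]]
      m * (p["hi"] - p["lo"]) + p["lo"]
    } else {
      m * params$stats$sd + params$stats$mean
    }
  }
  if (inherits(x, "session_ts"))
    return(session_ts(inv_mat(x$values, x$session_id),
                      x$sampling_interval, x$session_id))
  if (is.list(x)) return(lapply(x, unscale_signals, params = params))
  inv_mat(as.matrix(x), session)
}

#' Slice a session into overlapping past/future window pairs
#'
#' Windows advance with stride 1, so a session of length `T` yields
#' `T - t_p - t_f + 1` input-output pairs; the future block starts
#' immediately after the past block and windows never cross session
#' boundaries.
#'
#' @param x a `session_ts` or list of them
#' @param t_p,t_f lengths of the past (input) and future (target) sequences
#' @return a `gb_windows` object; see [window_sample()], [n_windows()],
#'   [split_windows()]
#' @export
make_windows <- function(x, t_p, t_f) {
  stopifnot(t_p >= 1L, t_f >= 1L)
  sessions <- if (inherits(x, "session_ts")) list(x) else x
  stopifnot(all(vapply(sessions, inherits, logical(1), "session_ts")))
  sess <- lapply(sessions, function(s) {
    tt <- ncol(s$values)
    if (tt < t_p + t_f)
      stop(sprintf("session '%s' too short: T = %d < t_p + t_f = %d",
                   s$session_id, tt, t_p + t_f))
    list(values = s$values, session_id = s$session_id,
         starts = seq_len(tt - t_p - t_f + 1L))
  })
  structure(list(sessions = sess, t_p = t_p, t_f = t_f),
            class = "gb_windows")
}

#' Number of window pairs in a `gb_windows` object
#' @param w a `gb_windows`
#' @export
n_windows <- function(w) {
  stopifnot(inherits(w, "gb_windows"))
  sum(vapply(w$sessions, function(s) length(s$starts), integer(1)))
}

# map a global window index to (session index, start)
gb_locate_window <- function(w, i) {
  counts <- vapply(w$sessions, function(s) length(s$starts), integer(1))
  ends <- cumsum(counts)
  si <- which(i <= ends)[1L]
  if (is.na(si) || i < 1L) stop("window index out of range")
  offset <- i - c(0L, ends)[si]
  list(session = si, start = w$sessions[[si]]$starts[offset])
}

#' Extract one window pair
#' @param w a `gb_windows`
#' @param i global window index (chronological within sessions, sessions in
#'   order)
#' @return list with `past` (N x t_p), `future` (N x t_f) and `origin`
#' @export
window_sample <- function(w, i) {
  loc <- gb_locate_window(w, i)
  s <- w$sessions[[loc$session]]
  past <- s$values[, loc$start:(loc$start + w$t_p - 1L), drop = FALSE]
  future <- s$values[, (loc$start + w$t_p):(loc$start + w$t_p + w$t_f - 1L),
                     drop = FALSE]
  list(past = past, future = future,
       origin = list(session_id = s$session_id, start = loc$start))
}

#' Gather a batch of windows into 3-d arrays
#' @param w a `gb_windows`
#' @param idx integer vector of global window indices
#' @return list with `past` (N x t_p x B) and `future` (N x t_f x B)
#' @export
window_batch <- function(w, idx) {
  n <- nrow(w$sessions[[1L]]$values)
  past <- array(0, c(n, w$t_p, length(idx)))
  future <- array(0, c(n, w$t_f, length(idx)))
  for (j in seq_along(idx)) {
    s <- window_sample(w, idx[j])
    past[, , j] <- s$past
    future[, , j] <- s$future
  }
  list(past = past, future = future)
}

#' Chronological train/validation/test split
#'
#' Within each session the final `floor(f_test * count)` pairs form the test
#' set, the preceding `floor(f_val * count)` pairs the validation set, and
#' everything earlier the training set; the splits are then aggregated across
#' sessions. With the default fractions a 1,200-step session windowed at
#' 60/60 yields 108 test pairs.
#'
#' @param w a `gb_windows`
#' @param fractions length-3 positive vector summing to 1 (train, val, test)
#' @return list of `gb_windows`: `train`, `val`, `test`
#' @export
split_windows <- function(w, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(w, "gb_windows"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  pick <- function(part) {
    sess <- lapply(w$sessions, function(s) {
      cnt <- length(s$starts)
      n_test <- floor(fractions[3L] * cnt)
      n_val <- floor(fractions[2L] * cnt)
      n_train <- cnt - n_val - n_test
      keep <- switch(part,
        train = seq_len(n_train),
        val = if (n_val > 0L) n_train + seq_len(n_val) else integer(0),
        test = if (n_test > 0L) n_train + n_val + seq_len(n_test) else integer(0))
      list(values = s$values, session_id = s$session_id,
           starts = s$starts[keep])
    })
    structure(list(sessions = sess, t_p = w$t_p, t_f = w$t_f),
              class = "gb_windows")
  }
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}

# -- delimited I/O -----------------------------------------------------------

#' Read a session matrix from delimited text
#' @param path TSV/CSV file, regions in rows; a header row of time indices is
#'   detected and skipped; an optional first column of region labels becomes
#'   row names
#' @param sampling_interval,session_id passed to [session_ts()];
#'   `session_id` defaults to the file name
#' @param sep field separator (guessed from the extension by default)
#' @param header set `TRUE` when the file carries a leading row of time
#'   indices
#' @export
read_session <- function(path, sampling_interval = 0.72, session_id = NULL,
                         sep = NULL, header = FALSE) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE,
                          skip = as.integer(isTRUE(header)))
  labels <- NULL
  if (is.character(df[[1L]])) {
    labels <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(labels)) rownames(m) <- labels
  if (is.null(session_id))
    session_id <- sub("\\.[^.]*$", "", basename(path))
  session_ts(m, sampling_interval, session_id)
}

#' Write a session matrix as delimited text
#' @param ts a `session_ts`
#' @param path output file
#' @param sep field separator
#' @export
write_session <- function(ts, path, sep = "\t") {
  utils::write.table(ts$values, path, sep = sep, quote = FALSE,
                     row.names = !is.null(rownames(ts$values)),
                     col.names = FALSE)
  invisible(path)
}

#' Read a weighted adjacency matrix
#'
#' Accepts either a square delimited matrix or a 3-column weighted edge list
#' (source, target, weight). Edge-list labels must match `regions` when
#' supplied; edges are symmetrized.
#'
#' @param path input file
#' @param regions optional character vector fixing the region order
#' @param kind adjacency kind label (`"SC"`, `"CE"` or `"synthetic"`)
#' @param sep field separator
#' @export
read_adjacency <- function(path, regions = NULL, kind = "SC", sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 3L && (is.character(df[[1L]]) || !is.null(regions))) {
    if (is.null(regions))
      regions <- sort(unique(c(as.character(df[[1L]]),
                               as.character(df[[2L]]))))
    n <- length(regions)
    a <- matrix(0, n, n, dimnames = list(regions, regions))
    i <- match(as.character(df[[1L]]), regions)
    j <- match(as.character(df[[2L]]), regions)
    if (anyNA(i) || anyNA(j))
      stop("edge list labels do not match the region order file")
    for (k in seq_len(nrow(df))) {
      a[i[k], j[k]] <- df[[3L]][k]
      a[j[k], i[k]] <- df[[3L]][k]
    }
  } else {
    a <- as.matrix(df)
    storage.mode(a) <- "double"
    if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
    dimnames(a) <- if (!is.null(regions)) list(regions, regions) else NULL
  }
  weighted_adjacency(a, kind)
}

#' Write an adjacency matrix as delimited text
#' @param adj a `weighted_adjacency` (or bare matrix)
#' @param path output file
#' @param sep field separator
#' @export
write_adjacency <- function(adj, path, sep = "\t") {
  m <- if (inherits(adj, "weighted_adjacency")) adj$weights else as.matrix(adj)
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region order file (one label per line)
#' @param path text file
#' @export
read_regions <- function(path) readLines(path)
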