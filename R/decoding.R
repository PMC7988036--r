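#' Fit a memoryless Poisson decoder
#'
#' Stores, for every visited map bin, each cell's expected firing rate
#' taken from its training-session rate map. Decoding assumes spike counts
#' in a time window are independent Poisson across cells with means
#' `lambda * tau` and a uniform prior over bins. At least 15 simultaneously
#' recorded place cells are required; training and test sessions must
#' differ (cross-session decoding avoids overfitting).
#'
#' @param training_maps List of [rate_map()]s, one per cell, from the same
#'   training session ("all data" maps).
#' @param tau Decoding window in s (default 0.3).
#' @param min_cells Minimum number of cells (default 15).
#' @param lambda_min Rate floor in Hz applied inside the likelihood so
#'   unvisited or silent bins never produce `log 0`.
#' @param train_label Optional session label, checked against the test
#'   session at decode time.
#' @param geometry A [maze_geometry()].
#' @return Object of class `poisson_decoder`: `lambda` (bins x cells,
#'   floored), bin coordinates and quadrants, `tau`, `grid`.
#' @export
fit_decoder <- function(training_maps, tau = 0.3, min_cells = 15,
                        lambda_min = 0.01, train_label = NULL,
                        geometry = maze_geometry()) {
  n_cells <- length(training_maps)
  if (n_cells < min_cells)
    stop("decoder requires at least ", min_cells,
         " simultaneously recorded place cells (got ", n_cells, ")")
  g <- training_maps[[1]]$grid
  valid <- Reduce(`&`, lapply(training_maps, function(m)
    !m$empty & is.finite(m$rate)))
  idx <- which(valid)
  if (!length(idx)) stop("no commonly visited bins to decode over")
  lambda <- vapply(training_maps, function(m) m$rate[idx],
                   numeric(length(idx)))
  lambda <- pmax(lambda, lambda_min)
  bx <- g$x0 + ((idx - 1L) %% g$nx) * g$bin + g$bin / 2
  by <- g$y0 + ((idx - 1L) %/% g$nx) * g$bin + g$bin / 2
  quad <- assign_region(bx, by, geometry, outside = "na")$quadrant
  keep <- !is.na(quad)
  structure(list(lambda = lambda[keep, , drop = FALSE],
                 bin_x = bx[keep], bin_y = by[keep],
                 quadrant = quad[keep], tau = tau, grid = g,
                 n_cells = n_cells, lambda_min = lambda_min,
                 train_label = train_label, geometry = geometry),
            class = "poisson_decoder")
}

#' @export
print.poisson_decoder <- function(x, ...) {
  cat(sprintf("poisson_decoder: %d cells, %d bins, tau = %g s%s\n",
              x$n_cells, length(x$bin_x), x$tau,
              if (!is.null(x$train_label))
                paste0(", trained on ", x$train_label) else ""))
  invisible(x)
}

#' Decode spike-count windows
#'
#' Log-domain Poisson likelihood accumulation with a uniform prior: for
#' window counts `sigma`, `log P(x) = sum_i sigma_i log(lambda_xi tau)
#' - lambda_xi tau + const`, normalized so the posterior sums to 1 over
#' bins. Arg-max ties break to the lowest bin index (or a seeded random
#' choice).
#'
#' @param model A [fit_decoder()] model.
#' @param counts Integer matrix (cells x windows) or vector for a single
#'   window.
#' @param tie_break `"lowest"` (default) or `"random"`.
#' @return List: `posterior` (bins x windows, columns sum to 1),
#'   `map_bin` (arg-max bin index per window), `quadrant` (decoded
#'   quadrant per window).
#' @export
decode_windows <- function(model, counts, tie_break = c("lowest", "random")) {
  tie_break <- match.arg(tie_break)
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  stopifnot(nrow(counts) == model$n_cells)
  logl <- log(model$lambda * model$tau) %*% counts -
    rowSums(model$lambda) * model$tau
  # normalize in log domain for numerical safety
  mx <- apply(logl, 2, max)
  post <- exp(sweep(logl, 2, mx))
  post <- sweep(post, 2, colSums(post), "/")
  map_bin <- apply(logl, 2, function(col) {
    w <- which(col == max(col))
    if (length(w) == 1 || tie_break == "lowest") w[1] else sample(w, 1)
  })
  list(posterior = post, map_bin = map_bin,
       quadrant = model$quadrant[map_bin])
}

#' @export
predict.poisson_decoder <- function(object, counts, ...) {
  decode_windows(object, counts, ...)
}

#' Decode a test session and build the quadrant confusion matrix
#'
#' The test session is cut into non-overlapping `tau` windows anchored at
#' the session start; windows with mean running speed below the threshold
#' are dropped. Each surviving window's population spike-count vector is
#' decoded to a map bin, then to one of the 16 box quadrants, and compared
#' with the animal's true quadrant (majority over the window's tracking
#' samples). Confusion rows (true quadrants) are normalized to probability
#' distributions.
#'
#' @param model A [fit_decoder()] model.
#' @param trajectory Test-session tracking data.
#' @param spikes_by_cell List of spike-time vectors, same cell order as the
#'   training maps.
#' @param test_label Optional label; must differ from the model's training
#'   session.
#' @param speed_threshold Minimum window speed (cm/s).
#' @return Object of class `decoding_result`: `confusion` (16 x 16
#'   counts), `confusion_prob` (row-normalized), `summary` (mean
#'   probability for correct quadrant, same-quadrant-wrong-box,
#'   same-box-wrong-quadrant, rest, plus the 1/16 chance level),
#'   `n_windows`.
#' @export
decode_session <- function(model, trajectory, spikes_by_cell,
                           test_label = NULL, speed_threshold = 5) {
  if (!is.null(test_label) && !is.null(model$train_label) &&
      identical(test_label, model$train_label))
    stop("training and test data must come from different sessions")
  stopifnot(length(spikes_by_cell) == model$n_cells)
  tau <- model$tau
  tt <- trajectory$t
  t_end <- tt[length(tt)]
  n_win <- floor(t_end / tau)
  if (n_win < 1) stop("test session shorter than one decoding window")
  win <- findInterval(tt, seq(0, n_win) * tau, rightmost.closed = FALSE)
  v <- compute_speed(trajectory)
  reg <- assign_region(trajectory$x, trajectory$y, model$geometry,
                       outside = "na")
  win_speed <- tapply(v, win, mean)[as.character(1:n_win)]
  true_quad <- vapply(1:n_win, function(w) {
    q <- reg$quadrant[win == w]
    q <- q[!is.na(q)]
    if (!length(q)) return(NA_integer_)
    as.integer(names(which.max(table(q))))
  }, integer(1))
  keep <- !is.na(win_speed) & win_speed >= speed_threshold &
    !is.na(true_quad)
  if (!any(keep)) stop("no decoding windows survive the speed filter")
  counts <- vapply(spikes_by_cell, function(s) {
    wb <- floor(s / tau) + 1L
    tabulate(wb[wb >= 1 & wb <= n_win], nbins = n_win)
  }, integer(n_win))
  counts <- t(counts[keep, , drop = FALSE])
  dec <- decode_windows(model, counts)
  confusion <- matrix(0L, 16, 16)
  tq <- true_quad[keep]
  for (k in seq_along(tq))
    confusion[tq[k], dec$quadrant[k]] <- confusion[tq[k], dec$quadrant[k]] + 1L
  rs <- rowSums(confusion)
  prob <- confusion / ifelse(rs == 0, NA, rs)
  same_quad <- outer(1:16, 1:16, function(i, j)
    (i - 1) %% 4 == (j - 1) %% 4 & i != j)
  same_box <- outer(1:16, 1:16, function(i, j)
    (i - 1) %/% 4 == (j - 1) %/% 4 & i != j)
  summary <- data.frame(
    category = c("correct", "same_quadrant_wrong_box",
                 "same_box_wrong_quadrant", "rest", "chance"),
    mean_probability = c(
      mean(diag(prob), na.rm = TRUE),
      mean(prob[same_quad], na.rm = TRUE),
      mean(prob[same_box], na.rm = TRUE),
      mean(prob[!same_quad & !same_box & diag(16) == 0], na.rm = TRUE),
      1 / 16))
  structure(list(confusion = confusion, confusion_prob = prob,
                 summary = summary, n_windows = sum(keep),
                 zero_rows = which(rs == 0)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result: %d windows\n", x$n_windows))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
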