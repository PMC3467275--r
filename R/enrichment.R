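# Poisson sliding-window enrichment calling with mock-control filtering.

#' Caller configuration
#'
#' @param window Window width in bp; must be a multiple of the track bin size.
#' @param step Pace between window starts in bp; `step <= window`.
#' @param p_threshold Significance threshold; windows with Poisson upper-tail
#'   p strictly below this are collected as enriched.
#' @param lambda_mode `"global"` (one genome-wide background rate) or
#'   `"per_chromosome"`.
#' @return List of class `caller_config`.
#' @export
caller_config <- function(window = 100, step = 100, p_threshold = 1e-5,
                          lambda_mode = c("global", "per_chromosome")) {
  lambda_mode <- match.arg(lambda_mode)
  if (step > window) stop("step must be <= window")
  if (step <= 0 || window <= 0) stop("window and step must be positive")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  structure(list(window = window, step = step, p_threshold = p_threshold,
                 lambda_mode = lambda_mode), class = "caller_config")
}

#' Estimate the Poisson background rate of a track
#'
#' The background rate per window is the mean midpoint count per window over
#' the scope: whole genome for `"global"`, each chromosome for
#' `"per_chromosome"` (lambda = total midpoints / number of windows, with
#' non-overlapping windows of the given width).
#'
#' @param track Raw `binned_track`.
#' @param mode Rate scope.
#' @param window Window width in bp.
#' @return For `"global"` a single rate; for `"per_chromosome"` a named vector.
#' @export
estimate_background_rate <- function(track, mode = c("global", "per_chromosome"),
                                     window = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "binned_track"))
  if (track$normalized) stop("background rate must be estimated on raw counts")
  nb <- vapply(track$bins, length, 0L)
  if (sum(nb) == 0 || sum(vapply(track$bins, sum, 0)) == 0) {
    stop("empty track: background rate undefined")
  }
  bins_per_window <- window / track$bin_size
  if (mode == "global") {
    sum(vapply(track$bins, sum, 0)) / sum(nb) * bins_per_window
  } else {
    vapply(track$bins, function(v) mean(v) * bins_per_window, 0)
  }
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed via the regularized gamma
#' function (stable for large rates).
#'
#' @param k Observed count (non-negative integer, vectorized).
#' @param lambda Poisson rate (> 0).
#' @return Upper-tail probability.
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Scan a track for significantly enriched windows
#'
#' Tests every window whose start is a multiple of `step` (windows fully
#' inside the chromosome) against the Poisson background; windows with
#' upper-tail p strictly below the threshold are returned.
#'
#' @param track Raw `binned_track`.
#' @param cfg A [caller_config()].
#' @param lambda Optional precomputed background rate per window (global
#'   scalar or per-chromosome named vector); estimated from the track when
#'   omitted.
#' @return data.frame with chrom, start, end, count, p for significant
#'   windows, ordered by chromosome then start.
#' @export
scan_windows <- function(track, cfg = caller_config(), lambda = NULL) {
  stopifnot(inherits(track, "binned_track"), inherits(cfg, "caller_config"))
  if (track$normalized) stop("scan_windows needs raw counts")
  bs <- track$bin_size
  if (cfg$window %% bs != 0 || cfg$step %% bs != 0) {
    stop("window and step must be multiples of the track bin size (", bs, ")")
  }
  wb <- cfg$window %/% bs
  sb <- cfg$step %/% bs
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      count = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (sum(vapply(track$bins, sum, 0)) == 0) return(empty)
  if (is.null(lambda)) {
    lambda <- estimate_background_rate(track, cfg$lambda_mode, cfg$window)
  }
  out <- lapply(names(track$bins), function(chrom) {
    v <- track$bins[[chrom]]
    n <- length(v)
    if (n < wb) return(NULL)
    lam0 <- if (length(lambda) > 1) lambda[[chrom]] else lambda
    if (lam0 == 0) return(NULL)
    starts <- seq(0L, n - wb, by = sb)
    if (wb == 1L) {
      k <- v[starts + 1L]
    } else {
      cs <- c(0, cumsum(v))
      k <- cs[starts + wb + 1L] - cs[starts + 1L]
    }
    p <- poisson_upper_tail(k, lam0)
    sig <- p < cfg$p_threshold
    if (!any(sig)) return(NULL)
    data.frame(chrom = chrom, start = starts[sig] * bs,
               end = (starts[sig] + wb) * bs, count = k[sig], p = p[sig],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  out
}

#' Merge significant windows into enriched regions
#'
#' Runs of windows that overlap or abut (gap 0) are merged into single
#' regions; each region records its best (minimum) p-value, maximum window
#' count and number of member windows. Output order is deterministic
#' (chromosome order of the input track, then start).
#'
#' @param windows Output of [scan_windows()].
#' @param cfg The caller configuration (unused beyond validation; kept for
#'   interface symmetry).
#' @return data.frame with chrom, start, end, min_p, max_count, n_windows.
#' @export
merge_windows <- function(windows, cfg = caller_config()) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      min_p = numeric(), max_count = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  windows <- windows[order(match(windows$chrom, unique(windows$chrom)),
                           windows$start), , drop = FALSE]
  res <- list()
  cur <- NULL
  flush <- function(cur) data.frame(chrom = cur$chrom, start = cur$start,
                                    end = cur$end, min_p = cur$min_p,
                                    max_count = cur$max_count,
                                    n_windows = cur$n, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$min_p <- min(cur$min_p, w$p)
      cur$max_count <- max(cur$max_count, w$count)
      cur$n <- cur$n + 1L
    } else {
      if (!is.null(cur)) res[[length(res) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, min_p = w$p,
                  max_count = w$count, n = 1L)
    }
  }
  res[[length(res) + 1L]] <- flush(cur)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Remove regions also enriched in the mock (anti-GFP) control
#'
#' For each candidate region the control midpoint count over the same span is
#' tested against the control's own background rate scaled to the span length;
#' regions whose control p-value is below the threshold are dropped.
#'
#' @param regions Output of [merge_windows()].
#' @param control_track Raw `binned_track` of the control sample.
#' @param cfg A [caller_config()].
#' @param lambda_source `"control"` (default) tests against the control
#'   sample's own background rate; `"ip"` uses the rate supplied in
#'   `ip_lambda`.
#' @param ip_lambda IP background rate per window, required for
#'   `lambda_source = "ip"`.
#' @return The surviving regions with `control_count` and `control_p` columns.
#' @export
filter_by_control <- function(regions, control_track, cfg = caller_config(),
                              lambda_source = c("control", "ip"),
                              ip_lambda = NULL) {
  lambda_source <- match.arg(lambda_source)
  if (nrow(regions) == 0) {
    regions$control_count <- numeric(0)
    regions$control_p <- numeric(0)
    return(regions)
  }
  stopifnot(inherits(control_track, "binned_track"))
  bs <- control_track$bin_size
  lam_w <- if (lambda_source == "control") {
    estimate_background_rate(control_track, cfg$lambda_mode, cfg$window)
  } else {
    if (is.null(ip_lambda)) stop("ip_lambda required for lambda_source = 'ip'")
    ip_lambda
  }
  k <- numeric(nrow(regions))
  p <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- control_track$bins[[regions$chrom[i]]]
    b1 <- regions$start[i] %/% bs + 1L
    b2 <- min(length(v), as.integer(ceiling(regions$end[i] / bs)))
    k[i] <- sum(v[b1:b2])
    lam <- if (length(lam_w) > 1) lam_w[[regions$chrom[i]]] else lam_w
    # pool the span as (span / window) background windows
    p[i] <- poisson_upper_tail(k[i], lam * (regions$end[i] - regions$start[i]) / cfg$window)
  }
  regions$control_count <- k
  regions$control_p <- p
  out <- regions[p >= cfg$p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call enriched regions from a raw track
#'
#' Convenience wrapper: estimate the background rate, scan windows, merge
#' them into regions, and (when a control track is given) drop regions also
#' enriched in the control.
#'
#' @param track Raw `binned_track` of the IP sample.
#' @param cfg A [caller_config()].
#' @param control_track Optional raw control track.
#' @param ... Passed on to [filter_by_control()].
#' @return Enriched regions data.frame.
#' @export
call_enriched_regions <- function(track, cfg = caller_config(),
                                  control_track = NULL, ...) {
  lambda <- estimate_background_rate(track, cfg$lambda_mode, cfg$window)
  regions <- merge_windows(scan_windows(track, cfg, lambda), cfg)
  if (!is.null(control_track)) {
    regions <- filter_by_control(regions, control_track, cfg, ...)
  }
  regions
}
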