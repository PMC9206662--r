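## End-member detrital-authigenic sediment mixing model.
##
## The sediment-expressed authigenic ratio is a mass-weighted mixture of an
## authigenic and a detrital end member:
##   f_s = M_a * f_a + (1 - M_a) * f_d
## Monte Carlo draws of (M_a, f_a, f_d) are filtered for mixtures that
## reproduce observed pre- and post-extinction sediment ratios.

#' Two-end-member mixing of sediment ratios
#'
#' `f_s = m_a * f_a + (1 - m_a) * f_d` with `m_d = 1 - m_a`.
#'
#' @param m_a Authigenic mass fraction in `[0, 1]` (vectorised).
#' @param f_a Authigenic-component ratio in `[0, 1]`.
#' @param f_d Detrital-component ratio in `[0, 1]`.
#' @return Sediment-expressed ratio `f_s`.
#' @export
mix <- function(m_a, f_a, f_d) {
  stopifnot(
    all(m_a >= 0 & m_a <= 1), all(f_a >= 0 & f_a <= 1),
    all(f_d >= 0 & f_d <= 1)
  )
  m_a * f_a + (1 - m_a) * f_d
}

#' Monte Carlo sampling and filtering of the mixing model
#'
#' Draws `n` triples with `M_a ~ U(0, 1)` (and `M_d = 1 - M_a`),
#' `f_a ~ U(0, 1)`, `f_d ~ U(f_d_range)`, computes the implied sediment
#' ratio, and classifies each draw against the pre- and post-extinction
#' sediment windows. Pre and post classifications are evaluated on
#' independent draws (sharing the sampling distributions), reflecting that
#' the two intervals are distinct sediment populations.
#'
#' @param n Number of draws per interval.
#' @param f_d_range Detrital-ratio sampling range (default `c(0, 0.15)`).
#' @param pre_range Accepted sediment-ratio window before the extinction
#'   (default `c(0, 0.15)`).
#' @param post_range Accepted window after the extinction; the two printed
#'   presets are `post_range = c(0.15, 0.55)` (full post-extinction spread)
#'   and `c(0.2, 0.3)` (observed central window).
#' @param seed Integer seed.
#' @return List of class `frw_mixing`: data frames `pre` and `post` of
#'   accepted draws (columns m_a, m_d, f_a, f_d, f_s), acceptance counts,
#'   and the filter settings. Empty accepted sets are flagged via
#'   `empty_pre` / `empty_post`.
#' @export
sample_and_filter <- function(n = 500000, f_d_range = c(0, 0.15),
                              pre_range = c(0, 0.15),
                              post_range = c(0.15, 0.55), seed = 1) {
  stopifnot(
    n >= 1, all(f_d_range >= 0 & f_d_range <= 1),
    all(pre_range >= 0 & pre_range <= 1),
    all(post_range >= 0 & post_range <= 1)
  )
  set.seed(seed)
  one_interval <- function(window) {
    m_a <- stats::runif(n)
    f_a <- stats::runif(n)
    f_d <- stats::runif(n, f_d_range[1], f_d_range[2])
    f_s <- mix(m_a, f_a, f_d)
    keep <- f_s >= window[1] & f_s <= window[2]
    data.frame(
      m_a = m_a[keep], m_d = 1 - m_a[keep], f_a = f_a[keep],
      f_d = f_d[keep], f_s = f_s[keep]
    )
  }
  pre <- one_interval(pre_range)
  post <- one_interval(post_range)
  structure(
    list(
      pre = pre, post = post, n = n,
      n_accept_pre = nrow(pre), n_accept_post = nrow(post),
      empty_pre = nrow(pre) == 0, empty_post = nrow(post) == 0,
      f_d_range = f_d_range, pre_range = pre_range, post_range = post_range,
      seed = seed
    ),
    class = "frw_mixing"
  )
}

#' @export
print.frw_mixing <- function(x, ...) {
  cat(sprintf(
    "<frw_mixing> n=%d: %d pre-window draws, %d post-window draws [%g, %g]\n",
    x$n, x$n_accept_pre, x$n_accept_post, x$post_range[1], x$post_range[2]
  ))
  invisible(x)
}

#' Summarise accepted mixing-model draws
#'
#' Histograms (fixed bin width) and distribution summaries of the accepted
#' mass fractions and authigenic ratio; the mode is the centre of the maximal
#' histogram bin.
#'
#' @param accepted Data frame of accepted draws (e.g. the `post` element of
#'   [sample_and_filter()]).
#' @param binwidth Histogram bin width on `[0, 1]` (default 0.025).
#' @return List of class `frw_mixing_summary` with per-variable `histogram`
#'   data frames and `stats` (min, max, mode, mean, quantiles 2.5/16/50/84/97.5%).
#' @export
summarize_mixing <- function(accepted, binwidth = 0.025) {
  stopifnot(nrow(accepted) > 0, binwidth > 0, binwidth <= 1)
  edges <- seq(0, 1, by = binwidth)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  vars <- c("m_d", "m_a", "f_a")
  out <- lapply(vars, function(v) {
    x <- accepted[[v]]
    counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
    hist_df <- data.frame(
      mid = (edges[-length(edges)] + edges[-1]) / 2,
      count = counts, density = counts / sum(counts) / binwidth
    )
    qs <- stats::quantile(x, c(0.025, 0.16, 0.5, 0.84, 0.975))
    list(
      histogram = hist_df,
      stats = c(
        min = min(x), max = max(x), mode = hist_df$mid[which.max(counts)],
        mean = mean(x), stats::setNames(qs, paste0("q", c("025", "16", "50",
                                                         "84", "975")))
      )
    )
  })
  names(out) <- vars
  structure(list(variables = out, binwidth = binwidth, n = nrow(accepted)),
            class = "frw_mixing_summary")
}

#' @export
print.frw_mixing_summary <- function(x, ...) {
  cat(sprintf("<frw_mixing_summary> %d accepted draws\n", x$n))
  for (v in names(x$variables)) {
    s <- x$variables[[v]]$stats
    cat(sprintf(
      "  %-3s min %.3f  mode %.3f  median %.3f  max %.3f\n",
      v, s["min"], s["mode"], s["q50"], s["max"]
    ))
  }
  invisible(x)
}

#' Acceptance probability of the mixing filter at fixed f_a
#'
#' Probability that a draw with the given authigenic ratio passes the
#' sediment-ratio window, computed by 2-D quadrature over the uniform
#' (M_a, f_d) sampling distributions. Serves as the independent check on the
#' Monte Carlo sampler.
#'
#' @param f_a Authigenic ratio (scalar or vector).
#' @param window Sediment-ratio acceptance window.
#' @param f_d_range Detrital-ratio sampling range.
#' @param n_grid Quadrature nodes per dimension.
#' @return Acceptance probability for each `f_a`.
#' @export
mixing_acceptance_prob <- function(f_a, window = c(0.2, 0.3),
                                   f_d_range = c(0, 0.15), n_grid = 2000) {
  vapply(f_a, function(fa) {
    ## midpoint rule over f_d; for each f_d the accepted M_a set is an
    ## interval computed analytically
    fd <- f_d_range[1] +
      (seq_len(n_grid) - 0.5) / n_grid * diff(f_d_range)
    lo <- window[1]
    hi <- window[2]
    frac <- vapply(fd, function(d) {
      if (abs(fa - d) < 1e-12) {
        return(as.numeric(d >= lo && d <= hi))
      }
      ## f_s = m*fa + (1-m)*d is monotone in m; invert the window
      m1 <- (lo - d) / (fa - d)
      m2 <- (hi - d) / (fa - d)
      mlo <- max(0, min(m1, m2))
      mhi <- min(1, max(m1, m2))
      max(0, mhi - mlo)
    }, numeric(1))
    mean(frac)
  }, numeric(1))
}
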