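#' Activation amplitudes across task difficulty levels
#'
#' The hypothesized activation curve relative to the minimum difficulty
#' level at which a region first activates: the amplitude is 0 below the
#' minimum level, 0.38 at the minimum level, and 0.62 / 0.82 / 0.92 /
#' 0.97 one to four levels above it.
#'
#' @param true_min_level Integer in `1..n_levels`, or `"inactive"` for a
#'   region that never activates.
#' @param n_levels Number of difficulty levels (default 5).
#' @return Object of class `halving_profile` with `true_min_level` and
#'   `amplitude_by_level` (length `n_levels`).
#' @export
halving_profile <- function(true_min_level, n_levels = 5) {
  offsets <- c(0.38, 0.62, 0.82, 0.92, 0.97)
  amp <- numeric(n_levels)
  if (!identical(true_min_level, "inactive")) {
    if (!true_min_level %in% seq_len(n_levels))
      stop("'true_min_level' must be in 1..", n_levels,
           " or \"inactive\"")
    idx <- seq(true_min_level, n_levels)
    amp[idx] <- offsets[seq_along(idx)]
  }
  structure(list(true_min_level = true_min_level,
                 amplitude_by_level = amp),
            class = "halving_profile")
}

#' Block paradigm of one difficulty level
#'
#' 8 s rest followed by a 3 s task stimulus, repeated 30 times and closed
#' by a final 8 s rest: 338 s, i.e. 169 volumes at TR 2.
#'
#' @param tr Repetition time (default 2 s).
#' @param n_cycles Number of rest+task cycles (default 30).
#' @return A [paradigm].
#' @export
halving_paradigm <- function(tr = 2, n_cycles = 30) {
  n_volumes <- as.integer((n_cycles * 11 + 8) / tr)
  # the 3 s stimulus is deliberately shorter than the TR; the sub-TR
  # boxcar is handled by fractional-coverage sampling
  suppressWarnings(
    make_block_paradigm("task", task_s = 3, rest_s = 8, tr = tr,
                        n_volumes = n_volumes))
}

#' Simulated ROI time-series generator for one subject
#'
#' Returns a generator that, queried at a difficulty level, produces that
#' level's ROI time series under the 8 s rest / 3 s task paradigm: a
#' constant baseline plus the level's amplitude times the HRF-convolved
#' task regressor, plus white Gaussian noise of standard deviation
#' `sigma`. Repeated queries at the same level reproduce the same series.
#'
#' @param profile A [halving_profile()].
#' @param sigma Noise standard deviation (default 1, giving a maximum SNR
#'   just below 1 at the top of the activation curve).
#' @param seed Optional integer; level series are drawn deterministically
#'   from `seed` without disturbing the caller's RNG.
#' @param baseline Constant signal baseline (default 100).
#' @param tr Repetition time (default 2 s).
#' @return A function `f(level)` returning a numeric series of 169
#'   volumes.
#' @export
make_halving_subject <- function(profile, sigma = 1, seed = NULL,
                                 baseline = 100, tr = 2) {
  stopifnot(inherits(profile, "halving_profile"), sigma > 0)
  par <- halving_paradigm(tr = tr)
  X <- build_design_matrix(par, double_gamma_hrf(tr = tr))
  reg <- X[, "task"]
  n <- par$n_volumes
  function(level) {
    if (!level %in% seq_along(profile$amplitude_by_level))
      stop("unknown difficulty level ", level)
    amp <- profile$amplitude_by_level[level]
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed + level)
    }
    baseline + amp * reg + stats::rnorm(n, sd = sigma)
  }
}

#' Binary-search tree over task difficulty levels
#'
#' Builds the decision tree of the halving algorithm for `n_levels`
#' ordered difficulty levels (1 = easiest). Each node tests one level;
#' under the monotonicity assumption (no activation at an easy level
#' implies none at easier ones... and conversely activation persists at
#' harder levels), an "active" outcome recurses on the strictly easier
#' candidate levels and an "inactive" outcome on the strictly harder
#' ones. The node level is the `ceiling(k / 2)`-th smallest of the `k`
#' remaining candidates, so five levels start at level 3 and every
#' subject is tested on at most `ceiling(log2(n_levels + 1))` levels.
#'
#' @param n_levels Number of difficulty levels (>= 1).
#' @return Root `halving_node`: nested lists with `level`, `on_active`,
#'   `on_inactive`; terminals are lists with a `label` (an integer level
#'   or `"inactive"`).
#' @export
build_halving_tree <- function(n_levels) {
  if (!is.numeric(n_levels) || n_levels < 1)
    stop("'n_levels' must be >= 1")
  recurse <- function(lo, hi, fallback) {
    if (lo > hi)
      return(structure(list(label = fallback), class = "halving_node"))
    m <- lo + ceiling((hi - lo + 1) / 2) - 1
    structure(list(level = m,
                   on_active = recurse(lo, m - 1, m),
                   on_inactive = recurse(m + 1, hi, fallback)),
              class = "halving_node")
  }
  recurse(1, n_levels, "inactive")
}

#' @export
print.halving_node <- function(x, indent = 0, branch = "", ...) {
  pad <- strrep("  ", indent)
  if (!is.null(x$label)) {
    cat(pad, branch, "-> ", x$label, "\n", sep = "")
  } else {
    cat(pad, branch, "test level ", x$level, "\n", sep = "")
    print(x$on_active, indent + 1, "[active]   ")
    print(x$on_inactive, indent + 1, "[inactive] ")
  }
  invisible(x)
}

#' Adaptive search for the minimum activating difficulty level
#'
#' Walks the halving tree: at each node the subject's ROI series for that
#' level is streamed through a single-series truncated SPRT (intercept +
#' one task regressor), and the verdict routes to an easier or harder
#' level. Returns the terminal classification and the total number of
#' 11 s rest+task blocks administered (partial blocks round up; each
#' level is capped at its 30 blocks).
#'
#' @param subject Per-level series generator from
#'   [make_halving_subject()] (or any `function(level)`).
#' @param tree Root node from [build_halving_tree()] (default 5 levels).
#' @param hyp [hypothesis()] tested at each level; default one-sided
#'   `H0: b = 0` vs `Ha: b >= 0.38`.
#' @param bounds [compute_boundaries()]; default alpha 0.05, beta 0.10,
#'   single test, truncation at the 169-volume level length.
#' @param tr Repetition time (default 2 s).
#' @param block_s Seconds per rest+task cycle (default 11).
#' @return List with `level` (integer or `"inactive"`), `blocks` (total
#'   blocks administered), `levels_tested` and `path` (per-level verdict
#'   and volumes).
#' @export
run_halving <- function(subject, tree = build_halving_tree(5),
                        hyp = hypothesis(c(0, 1), theta1 = 0.38,
                                         label = "roi"),
                        bounds = NULL, tr = 2, block_s = 11) {
  par <- halving_paradigm(tr = tr)
  if (is.null(bounds))
    bounds <- compute_boundaries(0.05, 0.10, n_tests = 1,
                                 truncation = par$n_volumes)
  max_blocks <- floor(par$n_volumes * tr / block_s)
  node <- tree
  blocks <- 0
  path <- list()
  while (is.null(node$label)) {
    y <- subject(node$level)
    run <- run_sequential(y, par, hyp, bounds = bounds, g_percent = 100,
                          smooth = FALSE, drift = FALSE)
    active <- run$classification[1, 1] == "Ha"
    used <- min(max_blocks, ceiling(run$stop_volume * tr / block_s))
    blocks <- blocks + used
    path[[length(path) + 1]] <- list(level = node$level, active = active,
                                     volumes = run$stop_volume,
                                     blocks = used)
    node <- if (active) node$on_active else node$on_inactive
  }
  list(level = node$label, blocks = blocks,
       levels_tested = length(path), path = path)
}

#' Fixed-design benchmark for the difficulty-level search
#'
#' Administers all levels in full (30 blocks each) and tests each level
#' with a one-sided GLM t-test of `H0: b = 0` vs `Ha: b > 0`. The subject
#' is classified at the easiest level whose test rejects, or
#' `"inactive"` when none does.
#'
#' @param subject Per-level series generator.
#' @param levels Levels administered (default `1:5`).
#' @param alpha Per-level significance level (default 0.05).
#' @param tr Repetition time (default 2 s).
#' @return List with `level` (integer or `"inactive"`), `blocks`
#'   (always `30 * length(levels)`) and `p_values`.
#' @export
run_halving_fixed <- function(subject, levels = 1:5, alpha = 0.05,
                              tr = 2) {
  par <- halving_paradigm(tr = tr)
  X <- build_design_matrix(par, double_gamma_hrf(tr = tr))
  p <- vapply(levels, function(l)
    glm_ttest(X, subject(l), c(0, 1))$p_value, numeric(1))
  p[is.na(p)] <- 1  # degenerate zero-variance null series: no rejection
  rej <- levels[p < alpha]
  list(level = if (length(rej)) min(rej) else "inactive",
       blocks = 30 * length(levels), p_values = stats::setNames(p, levels))
}

#' Monte-Carlo study of the difficulty-level designs
#'
#' Simulates `n_subjects` ROI signals per true minimum level (1..5 and
#' inactive) and classifies each subject with the adaptive
#' halving + SPRT design ([run_halving()]) or the 150-block fixed design
#' ([run_halving_fixed()]). Produces the confusion matrix of classified
#' versus true levels, per-group accuracy, and (for the sequential arm)
#' mean and SD of blocks administered and scan-time savings versus the
#' 150-block benchmark.
#'
#' @param n_subjects Subjects per true-level group (default 100).
#' @param sigma Noise SD (default 1).
#' @param seed Base integer seed; subject `i` of group `g` draws from
#'   seed `seed + 1000 g + 10 i`.
#' @param method `"sprt"` (halving + SPRT) or `"fixed"`.
#' @param alpha,beta Error rates of the per-level tests (`beta` is used
#'   by the SPRT arm only).
#' @param delta One-sided alternative amplitude of the SPRT (default
#'   0.38).
#' @return List with `confusion` (classified x true counts), `accuracy`
#'   (percent per group), `mean_blocks`, `sd_blocks`, `savings`
#'   (percent vs 150 blocks).
#' @export
simulate_halving_study <- function(n_subjects = 100, sigma = 1, seed = 1,
                                   method = c("sprt", "fixed"),
                                   alpha = 0.05, beta = 0.10,
                                   delta = 0.38) {
  method <- match.arg(method)
  groups <- c(1:5, "inactive")
  lev_names <- c(as.character(1:5), "inactive")
  confusion <- matrix(0L, 6, 6, dimnames = list(classified = lev_names,
                                                true = lev_names))
  blocks <- matrix(NA_real_, n_subjects, 6,
                   dimnames = list(NULL, lev_names))
  tree <- build_halving_tree(5)
  hyp <- hypothesis(c(0, 1), theta1 = delta, label = "roi")
  bounds <- compute_boundaries(alpha, beta, 1, truncation = 169)
  for (g in seq_along(groups)) {
    true <- if (groups[g] == "inactive") "inactive" else as.integer(groups[g])
    prof <- halving_profile(true)
    for (i in seq_len(n_subjects)) {
      subj <- make_halving_subject(prof, sigma = sigma,
                                   seed = seed + 1000L * g + 10L * i)
      res <- if (method == "sprt")
        run_halving(subj, tree, hyp, bounds)
      else run_halving_fixed(subj, alpha = alpha)
      confusion[as.character(res$level), lev_names[g]] <-
        confusion[as.character(res$level), lev_names[g]] + 1L
      blocks[i, g] <- res$blocks
    }
  }
  accuracy <- 100 * diag(confusion) / colSums(confusion)
  mean_blocks <- colMeans(blocks)
  list(confusion = confusion,
       accuracy = stats::setNames(accuracy, lev_names),
       mean_blocks = mean_blocks,
       sd_blocks = apply(blocks, 2, stats::sd),
       savings = scan_savings(mean_blocks, 150))
}
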