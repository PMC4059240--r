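# Closed-form null models for the unfolded SFS: the constant-N neutral
# spectrum, the ancestral-state-misassignment (ASM) posterior-odds model, the
# ASM forward model for presented spectra, and the binomial sequencing-error
# mixing model, with the deterministic solvers built on them.

#' Harmonic number a_k = sum(1/i, i = 1..k-1)
#'
#' The Watterson correction factor for a sample of `k` sequences.
#'
#' @param k Sample size (>= 2).
#' @return `sum(1/(1:(k-1)))`.
#' @export
harmonic_a <- function(k) {
  stopifnot(k >= 2)
  sum(1 / seq_len(k - 1))
}

#' Neutral unfolded site frequency spectrum
#'
#' Under a constant-size Wright-Fisher neutral model the relative frequency of
#' polymorphic sites with `d` derived copies is proportional to `1/d`, so the
#' expected mean derived count is `(k - 1) / a_k`. For `k = 11` this gives
#' mean 3.414 and a singleton share of 34.1%.
#'
#' @param k Sample size (>= 2).
#' @return A tibble with columns `d` (1..k-1) and `prop` (summing to 1).
#' @export
neutral_sfs <- function(k) {
  stopifnot(k >= 2)
  d <- seq_len(k - 1)
  tibble::tibble(d = d, prop = (1 / d) / harmonic_a(k))
}

#' Expected mean derived count of the neutral SFS
#'
#' @inheritParams neutral_sfs
#' @param exclude_singletons Drop the classes `d = 1` and `d = k - 1`
#'   (apparent singletons under either polarity) before taking the mean;
#'   requires `k >= 4`.
#' @return Expected mean `d`.
#' @export
neutral_mean_d <- function(k, exclude_singletons = FALSE) {
  if (!exclude_singletons) {
    return((k - 1) / harmonic_a(k))
  }
  if (k < 4) stop("nonsingleton mean requires k >= 4", call. = FALSE)
  d <- 2:(k - 2)
  sum(d * (1 / d)) / sum(1 / d)
}

#' Parameters of the neutral/ASM null model
#'
#' Bundles the sample size `k`, per-site diversity `theta` (Watterson),
#' per-site outgroup divergence `div`, and the derived outgroup-branch
#' quantity `b = div - ((k - 1) / k) * theta` — the expected density of
#' substitutions on the branch joining the outgroup to the ingroup ancestor,
#' which sets the prior odds of ancestral-state misassignment. Optionally a
#' per-base per-sequence error rate `eps`.
#'
#' @param k Sample size (>= 2).
#' @param theta Per-site Watterson diversity (>= 0).
#' @param div Per-site divergence from the outgroup.
#' @param eps Sequencing error rate in `[0, 1)`.
#' @return A list of class `neutral_model_params`.
#' @export
neutral_model_params <- function(k = 11, theta = NULL, div = NULL, eps = 0) {
  stopifnot(k >= 2, eps >= 0, eps < 1)
  b <- if (!is.null(theta) && !is.null(div)) div - (k - 1) / k * theta else NULL
  structure(
    list(k = k, theta = theta, div = div, b = b, eps = eps),
    class = "neutral_model_params"
  )
}

#' Posterior odds that parsimony polarization is correct
#'
#' For a site with `d` of `k` sequences carrying the apparent derived state,
#' the likelihood ratio of correct assignment to ASM under the neutral SFS is
#' `(k - d) / d`, and the prior odds of no substitution versus one
#' substitution on the outgroup branch are `1 / b` with
#' `b = div - ((k - 1) / k) * theta`. The posterior odds are their product;
#' the ASM probability is `1 / (1 + odds)`.
#'
#' @param d Derived count(s), `1 <= d <= k - 1`.
#' @param params A [neutral_model_params()] with `theta` and `div` set (or a
#'   direct numeric `b` via the `b` argument).
#' @param b Optionally the branch quantity directly, overriding `params`.
#' @return A tibble with columns `d`, `likelihood_ratio`, `odds`, `p_asm`.
#' @export
posterior_odds <- function(d, params = NULL, b = NULL) {
  if (is.null(b)) {
    stopifnot(inherits(params, "neutral_model_params"))
    b <- params$b
    k <- params$k
  } else {
    k <- if (!is.null(params)) params$k else 11
  }
  if (is.null(b) || b <= 0) {
    stop("prior odds undefined: b = div - ((k-1)/k) * theta must be > 0",
      call. = FALSE
    )
  }
  stopifnot(all(d >= 1), all(d <= k - 1))
  lr <- (k - d) / d
  odds <- lr / b
  tibble::tibble(d = d, likelihood_ratio = lr, odds = odds, p_asm = 1 / (1 + odds))
}

#' ASM forward model: presented SFS after polarity flips
#'
#' Takes a true spectrum over `d = 1..k-1` and flips each site's polarity
#' (`d -> k - d`) with probability `f = b / (1 + b)`, the probability of one
#' (rather than no) substitution on the outgroup branch. Probability mass is
#' conserved: `presented_d = p_d (1 - f) + p_{k-d} f`.
#'
#' @param props Numeric vector of true proportions over `d = 1..k-1` (must
#'   sum to 1), e.g. `neutral_sfs(k)$prop`.
#' @param b Outgroup-branch quantity (>= 0); alternatively supply `params`.
#' @param params A [neutral_model_params()].
#' @return A tibble with columns `d`, `true_prop`, `presented_prop`.
#' @export
asm_forward_sfs <- function(props, b = NULL, params = NULL) {
  if (is.null(b)) {
    stopifnot(inherits(params, "neutral_model_params"))
    b <- params$b
  }
  stopifnot(b >= 0)
  if (abs(sum(props) - 1) > 1e-8 || any(props < 0)) {
    stop("`props` must be nonnegative proportions summing to 1", call. = FALSE)
  }
  f <- b / (1 + b)
  presented <- props * (1 - f) + rev(props) * f
  tibble::tibble(
    d = seq_along(props), true_prop = props,
    presented_prop = presented
  )
}

#' Divergence at which ASM equalizes the high-frequency tail
#'
#' Solves for the per-site divergence that makes the presented proportions of
#' sites with `k - 2` and `k - 1` derived states equal under the ASM forward
#' model on the neutral SFS. Closed form: the flip odds must satisfy
#' `b = (1/(k-2) - 1/(k-1)) / (1 - 1/2)` (low-frequency classes 1 and 2 feed
#' the tail, tail classes drain back), then
#' `div = b + ((k - 1)/k) * theta`.
#'
#' @param theta Per-site Watterson diversity.
#' @param k Sample size (>= 4).
#' @return A list with `div` (the solved divergence), `b`, and
#'   `tail_prop` (the common presented proportion in classes `k-2` and `k-1`).
#' @export
solve_equal_tail_divergence <- function(theta, k = 11) {
  stopifnot(k >= 4, theta >= 0)
  b <- (1 / (k - 2) - 1 / (k - 1)) / (1 - 1 / 2)
  fwd <- asm_forward_sfs(neutral_sfs(k)$prop, b = b)
  list(
    div = b + (k - 1) / k * theta,
    b = b,
    tail_prop = fwd$presented_prop[k - 1]
  )
}

#' Ratio of presented (k-1) to (k-2) classes under ASM
#'
#' @param params A [neutral_model_params()] with `theta` and `div`.
#' @return The presented-proportion ratio of the top two derived classes
#'   (10:9 for k = 11); 0.9 at `b = 0`, rising with divergence.
#' @export
asm_tail_ratio <- function(params) {
  k <- params$k
  fwd <- asm_forward_sfs(neutral_sfs(k)$prop, params = params)
  fwd$presented_prop[k - 1] / fwd$presented_prop[k - 2]
}

#' Binomial sequencing-error mixing matrix
#'
#' Probability of observing `j` derived copies given a true derived count
#' `d`, for independent per-sequence errors at rate `eps` that all produce
#' the derived state (so errors only convert ancestral copies):
#' a truly invariant site (`d = 0`, all `k` copies ancestral) presents `j`
#' derived with probability `C(k, j) eps^j (1-eps)^(k-j)`; a true class-`d`
#' site presents `d + j` with probability
#' `C(k-d, j) eps^j (1-eps)^(k-d-j)`. A site whose every copy ends up derived
#' presents as invariant for the other allele (observed column `k` maps out
#' of the polymorphic range).
#'
#' @param k Sample size.
#' @param eps Error rate in `[0, 1)`.
#' @return A `k x (k + 1)` matrix; rows are true classes `0..k-1`, columns
#'   observed classes `0..k`, each row summing to 1.
#' @export
error_mixing_matrix <- function(k, eps) {
  stopifnot(eps >= 0, eps < 1)
  m <- matrix(0, nrow = k, ncol = k + 1,
              dimnames = list(true = 0:(k - 1), observed = 0:k))
  for (d in 0:(k - 1)) {
    j <- 0:(k - d)
    m[d + 1, d + 1 + j] <- stats::dbinom(j, k - d, eps)
  }
  m
}

#' Apparent derived-singleton fraction under sequencing error
#'
#' Mixes the true per-site class frequencies of a neutral constant-size
#' population — invariant with frequency `1 - theta * a_k`, derived class `d`
#' with frequency `theta / d` — through [error_mixing_matrix()], and returns
#' the share of observed polymorphic sites (observed class 1..k-1) that are
#' observed singletons. At `eps = 0` this is the neutral `1 / a_k` (34.1% for
#' k = 11).
#'
#' @param theta Per-site diversity (`theta * a_k` must be < 1).
#' @param k Sample size.
#' @param eps Error rate.
#' @return Observed-singleton fraction among observed polymorphic sites.
#' @export
apparent_singleton_fraction <- function(theta, k, eps) {
  a <- harmonic_a(k)
  stopifnot(theta >= 0, theta * a < 1)
  freq <- c(1 - theta * a, theta / seq_len(k - 1)) # true classes 0..k-1
  obs <- as.numeric(freq %*% error_mixing_matrix(k, eps))
  poly <- obs[2:k] # observed classes 1..k-1
  poly[1] / sum(poly)
}

#' Error rate matching an observed apparent-singleton fraction
#'
#' Inverts [apparent_singleton_fraction()] (strictly increasing in `eps`) by
#' bracketed bisection.
#'
#' @inheritParams apparent_singleton_fraction
#' @param target Observed singleton fraction, above the `eps = 0` baseline
#'   `1 / a_k` and below 1.
#' @param upper Upper bracket for the root search (kept within the
#'   low-error regime where the singleton fraction is increasing in `eps`).
#' @return The error rate `eps`.
#' @export
solve_error_rate <- function(theta, k, target, upper = 0.05) {
  baseline <- apparent_singleton_fraction(theta, k, 0)
  if (target < baseline - 1e-12 || target >= 1) {
    stop("target singleton fraction must lie in [", signif(baseline, 4),
      ", 1)",
      call. = FALSE
    )
  }
  if (target <= baseline + 1e-12) {
    return(0)
  }
  stats::uniroot(
    function(e) apparent_singleton_fraction(theta, k, e) - target,
    interval = c(0, upper), tol = 1e-10
  )$root
}
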