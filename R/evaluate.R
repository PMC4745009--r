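#' Summarise posterior behavioural states
#'
#' Per-time posterior mean state (continuous in `[1, 2]`), posterior median
#' state, and probability of the ARS state, pooled over all retained draws
#' and chains. The mean encodes estimation uncertainty: values near 1 or 2
#' are confident, values near 1.5 are maximally uncertain, and the identity
#' `mean = 1 + P(state 2)` holds exactly.
#'
#' @param draws state draws for one track: an `n_draws x T` matrix or an
#'   `n_draws x T x n_chains` array of values in `{1, 2}`, or an `ssm_fit`.
#' @param track for an `ssm_fit`, which track to summarise (default 1).
#' @return Data frame with columns `t`, `mean`, `median`, `p_ars`.
#' @export
summarise_states <- function(draws, track = 1) {
  if (inherits(draws, "ssm_fit")) draws <- draws$states[[track]]
  if (length(dim(draws)) == 3) {
    d <- dim(draws)
    draws <- matrix(aperm(draws, c(1, 3, 2)), d[1] * d[3], d[2])
  }
  draws <- as.matrix(draws)
  if (nrow(draws) == 0) stop("empty draws", call. = FALSE)
  p2 <- colMeans(draws == 2)
  data.frame(t = seq_len(ncol(draws)), mean = 1 + p2,
             median = ifelse(p2 > 0.5, 2, ifelse(p2 < 0.5, 1, 1.5)),
             p_ars = p2)
}

#' Behavioural-state root-mean-squared error
#'
#' RMSE between per-time posterior mean states and the true simulated
#' states. Because the posterior mean ranges continuously between 1 and 2,
#' this metric penalises estimation uncertainty as well as outright
#' misclassification; for two-state truth it is bounded by `[0, 1]`.
#'
#' @param summary a [summarise_states()] result (or any object with a
#'   `mean` column), or a numeric vector of posterior mean states.
#' @param truth integer vector of true states in `{1, 2}`.
#' @return Scalar RMSE.
#' @export
state_rmse <- function(summary, truth) {
  est <- if (is.numeric(summary)) summary else summary$mean
  if (length(est) != length(truth))
    stop("estimate and truth lengths differ", call. = FALSE)
  sqrt(mean((est - truth)^2))
}

#' Cohen's kappa for posterior median states
#'
#' Chance-corrected agreement between posterior median states and truth.
#' Ties (posterior median exactly 1.5, which is rare) are assigned to the
#' transient state by default. Degenerate tables in which either sequence
#' uses a single state return `NA` with a warning, as kappa is undefined
#' there.
#'
#' @param median_states numeric vector of posterior median states
#'   (values in `{1, 1.5, 2}`).
#' @param truth integer vector of true states in `{1, 2}`.
#' @param tie_state state assigned to exact ties (default 1).
#' @return Scalar kappa in `[-1, 1]`, or `NA` for a degenerate table.
#' @export
kappa_states <- function(median_states, truth, tie_state = 1) {
  if (length(median_states) != length(truth))
    stop("estimate and truth lengths differ", call. = FALSE)
  est <- ifelse(median_states == 1.5, tie_state, median_states)
  tab <- table(factor(est, levels = 1:2), factor(truth, levels = 1:2))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warning("degenerate agreement table: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Potential scale reduction factor (R-hat)
#'
#' Brooks-Gelman-Rubin convergence diagnostic from the between/within-chain
#' variance decomposition, computed on retained (post burn-in, thinned)
#' draws: `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate that
#' the chains have mixed; the conventional acceptance threshold is 1.1.
#' A rank-normalised variant (computed on the normal scores of the pooled
#' ranks) is available via `rank_normalise = TRUE`.
#'
#' @param chains `n x m` matrix of draws (one column per chain), or a list
#'   of equal-length numeric vectors.
#' @param rank_normalise apply rank-normalisation first (default FALSE).
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains, rank_normalise = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2) stop("need >= 2 chains", call. = FALSE)
  if (n < 10) stop("need >= 10 retained draws per chain", call. = FALSE)
  if (rank_normalise) {
    r <- rank(as.vector(chains), ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
    chains <- matrix(z, n, m)
  }
  W <- mean(apply(chains, 2, var))
  if (W == 0) stop("zero within-chain variance: R-hat undefined",
                   call. = FALSE)
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `prob` of the draws:
#' scans all windows of `ceiling(prob * n)` sorted draws and returns the
#' narrowest.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob coverage probability in (0, 1), default 0.95.
#' @return Length-2 vector `(lower, upper)`.
#' @export
hpdi <- function(draws, prob = 0.95) {
  if (length(draws) == 0) stop("empty draws", call. = FALSE)
  if (prob <= 0 || prob >= 1) stop("`prob` must be in (0, 1)", call. = FALSE)
  s <- sort(draws)
  n <- length(s)
  k <- min(ceiling(prob * n), n)
  if (k == n) return(c(s[1], s[n]))
  w <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(w)
  c(s[i], s[i + k])
}

#' Compare SSM and hSSM behavioural-state estimation across scenarios
#'
#' For each scenario: simulates the tracks, fits one joint hSSM across all
#' of them and an independent SSM to each, and records the per-track
#' behavioural-state RMSE under both model forms. A failed fit is recorded
#' as `NA` with a warning rather than aborting the study.
#'
#' @param scenarios list of [scenario()] objects.
#' @param fit_config_hssm,fit_config_ssm [fit_config()] templates for the
#'   two arms; their `obs` and `seed` are overridden per scenario.
#' @return Object of class `comparison_table`: a data frame with columns
#'   `scenario`, `model`, `track`, `rmse`, with scenario-level medians and
#'   quartiles in `attr(, "summary")`.
#' @export
run_comparison_study <- function(scenarios,
                                 fit_config_hssm = fit_config("hssm"),
                                 fit_config_ssm = fit_config("ssm")) {
  rows <- list()
  for (scn in scenarios) {
    sims <- simulate_scenario(scn)
    truths <- lapply(sims, function(s) s$truth$b)
    cfg_h <- fit_config_hssm
    cfg_h$obs <- scn$obs
    cfg_h$seed <- (scn$seed + 104729L) %% 2147483647L
    cfg_s <- fit_config_ssm
    cfg_s$obs <- scn$obs
    cfg_s$seed <- (scn$seed + 224737L) %% 2147483647L
    hfit <- tryCatch(fit(sims, cfg_h), error = function(e) {
      warning("hSSM fit failed for ", scn$id, ": ", conditionMessage(e))
      NULL
    })
    for (k in seq_along(sims)) {
      rm_h <- if (!is.null(hfit))
        state_rmse(trim_summary(summarise_states(hfit, k), truths[[k]]),
                   truths[[k]]) else NA_real_
      sfit <- tryCatch(fit(sims[[k]], cfg_s), error = function(e) {
        warning("SSM fit failed for ", sims[[k]]$track_id, ": ",
                conditionMessage(e))
        NULL
      })
      rm_s <- if (!is.null(sfit))
        state_rmse(trim_summary(summarise_states(sfit, 1), truths[[k]]),
                   truths[[k]]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scn$id,
        model = c("hssm", "ssm"), track = sims[[k]]$track_id,
        rmse = c(rm_h, rm_s))
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, list(out$scenario, out$model)),
    function(d) data.frame(scenario = d$scenario[1], model = d$model[1],
                           median = median(d$rmse, na.rm = TRUE),
                           q25 = unname(quantile(d$rmse, 0.25, na.rm = TRUE)),
                           q75 = unname(quantile(d$rmse, 0.75, na.rm = TRUE)))))
  rownames(smry) <- NULL
  structure(out, summary = smry, class = c("comparison_table", "data.frame"))
}

# posterior mean states can cover one extra latent step when the final
# observation falls inside a step; trim to the truth length
trim_summary <- function(s, truth) s$mean[seq_along(truth)]
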