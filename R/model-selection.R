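#' Compare numbers of clusters by held-out predictive log-likelihood
#'
#' Masks a random fraction of observed cells, fits the model for each
#' candidate K on the remaining cells, and scores the masked cells under the
#' fitted posterior predictive (mixing the sensitized and nonsensitized
#' emission posterior means over the component's class posterior and the
#' child's sensitization posterior). Larger is better. The default K = 3 of
#' [model_config()] reflects the structure this package targets; this
#' utility is how a user can check it on their own cohort.
#'
#' @param x Observation matrix (0/1 or 0..3).
#' @param config Base `model_config`; its K is replaced by each candidate.
#' @param Ks Candidate cluster counts (default 2:6).
#' @param seed Seed for the mask and the fits.
#' @param heldout_frac Fraction of observed cells to mask (default 0.1).
#' @param n_restarts Restarts per fit (default 4, for speed).
#' @return data.frame with `K`, `heldout_loglik`, `n_heldout`, `converged`.
#' @export
compare_k <- function(x, config = model_config(), Ks = 2:6, seed = 1L,
                      heldout_frac = 0.1, n_restarts = 4L) {
  xm <- as_latent_input(x, config$emission_mode)
  set.seed(derive_seed(seed, "heldout-mask"))
  obs <- which(!is.na(xm))
  hold <- sample(obs, max(1L, round(heldout_frac * length(obs))))
  xtrain <- xm
  xtrain[hold] <- NA_integer_
  C <- if (config$emission_mode == "binary") 2L else 4L
  rows <- lapply(Ks, function(K) {
    cfg <- config
    cfg$K <- as.integer(K)
    ps <- suppressWarnings(
      fit_approximate(xtrain, cfg, seed = derive_seed(seed, "heldout-fit", K),
                      n_restarts = n_restarts, canonical = FALSE)
    )
    idx <- arrayInd(hold, dim(xm))
    ll <- vapply(seq_len(nrow(idx)), function(t) {
      i <- idx[t, 1L]; j <- idx[t, 2L]; cobs <- xm[i, j] + 1L
      phi <- ps$membership[j, ]
      pc <- 0
      for (k in seq_len(K)) {
        pc <- pc + phi[k] * (ps$sensitization[i, k] * ps$emission$pos[j, cobs] +
                               (1 - ps$sensitization[i, k]) * ps$emission$neg[j, cobs])
      }
      if (length(phi) > K) pc <- pc + phi[K + 1L] * ps$emission$neg[j, cobs]
      log(max(pc, 1e-300))
    }, 0)
    data.frame(K = K, heldout_loglik = sum(ll), n_heldout = length(hold),
               converged = isTRUE(ps$converged))
  })
  do.call(rbind, rows)
}
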