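# Two-state hidden Markov model over informative markers.
#
# The hidden state at each informative marker is which of the carrier
# parent's two haplotypes (0 = disease-linked, 1 = normal) the embryo
# inherited there. Transitions between adjacent markers at distance d bp
# follow a Haldane (no-interference) map at recombination rate r per bp:
# p_switch = (1 - exp(-2 r d)) / 2. The observation at each marker is the
# allele the embryo received from the carrier parent (deducible because the
# other parent is homozygous at informative markers). The emission accounts
# for MDA allele dropout under the surviving-allele convention -- dropout
# both hides sites and, when the non-transmitted-side allele survives alone,
# mimics the opposite haplotype -- plus a random genotype-error flip; see
# emission_logp() for the derivation.

#' HMM parameters for embryo haplotype decoding
#'
#' @param ado_rate Per-allele dropout probability during whole-genome
#'   amplification (surviving-allele convention). Default 0.10, a
#'   conventional MDA dropout magnitude.
#' @param geno_error Probability a surviving allele is miscalled. Default
#'   0.01.
#' @param recomb_rate Per-base-pair crossover probability; default 1e-8
#'   (about 1 cM/Mb).
#' @param min_posterior Posterior required at the gene interval to issue a
#'   carrier/non-carrier verdict; default 0.95.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(ado_rate = 0.10, geno_error = 0.01,
                       recomb_rate = 1e-8, min_posterior = 0.95) {
  stopifnot(ado_rate >= 0, ado_rate < 1, geno_error >= 0, geno_error < 1,
            ado_rate + geno_error < 1,
            recomb_rate >= 0, min_posterior > 0.5, min_posterior <= 1)
  structure(list(ado_rate = ado_rate, geno_error = geno_error,
                 recomb_rate = recomb_rate, min_posterior = min_posterior),
            class = "hmm_params")
}

# Emission log-probabilities for one observation under both states.
# obs: transmitted allele (0/1 allele value) or NA; a0/a1: the state
# haplotype alleles at this marker.
#
# Derived from the per-allele dropout process with the surviving-allele
# convention. At an informative marker the embryo's two alleles are the
# transmitted allele t and the other parent's allele b, equal with
# probability ~1/2 across markers:
#   - t != b (embryo het): both alleles drop (ado^2) or b's survivor makes
#     t undeducible (ado*(1-ado)) -> no observation; the t-dropout survivor
#     mimics the other haplotype (ado*(1-ado)) -> wrong observation;
#   - t == b (embryo hom): lost only when both drop (ado^2), never wrong.
# Marginalizing the two cases and adding the genotype-error flip when both
# alleles survive:
#   P(missing) = (ado + ado^2)/2
#   P(wrong)   = ado*(1-ado)/2 + (1-ado)^2 * err
#   P(correct) = 1 - P(missing) - P(wrong)
emission_logp <- function(obs, a0, a1, params) {
  ado <- params$ado_rate
  err <- params$geno_error
  p_na <- (ado + ado^2) / 2
  p_wrong <- ado * (1 - ado) / 2 + (1 - ado)^2 * err
  p_correct <- 1 - p_na - p_wrong
  if (is.na(obs)) {
    p <- max(p_na, 1e-12) # floored so a stray missing obs at ado = 0 stays finite
    return(c(log(p), log(p)))
  }
  c(log(max(if (obs == a0) p_correct else p_wrong, 1e-12)),
    log(max(if (obs == a1) p_correct else p_wrong, 1e-12)))
}

switch_prob <- function(d, r) (1 - exp(-2 * r * d)) / 2

#' Decode an embryo's transmitted haplotype with the two-state HMM
#'
#' Runs Viterbi (maximum a posteriori path) and forward-backward (per-marker
#' posteriors) over the informative markers.
#'
#' @param obs Integer vector of observed transmitted alleles (values matching
#'   the allele coding of `hap0`/`hap1`; `NA` for missing or undeducible).
#' @param hap0,hap1 Allele vectors of the carrier parent's disease-linked and
#'   normal haplotypes at the same markers (`hap0[i] != hap1[i]`).
#' @param pos Marker positions (bp), strictly increasing.
#' @param params An [hmm_params()] object.
#' @return A tibble with columns `pos`, `obs`, `state` (Viterbi), `post0`,
#'   `post1` (forward-backward posteriors). Zero-row input gives a zero-row
#'   tibble.
#' @export
hmm_decode <- function(obs, hap0, hap1, pos, params = hmm_params()) {
  n <- length(obs)
  stopifnot(length(hap0) == n, length(hap1) == n, length(pos) == n)
  if (n == 0L) {
    return(tibble::tibble(pos = integer(), obs = integer(), state = integer(),
                          post0 = numeric(), post1 = numeric()))
  }
  if (any(hap0 == hap1, na.rm = TRUE)) {
    abort("hap0 and hap1 must differ at every informative marker")
  }
  if (n > 1 && is.unsorted(pos, strictly = TRUE)) {
    abort("marker positions must be strictly increasing")
  }

  em <- matrix(0, nrow = n, ncol = 2)
  for (i in seq_len(n)) em[i, ] <- emission_logp(obs[[i]], hap0[[i]], hap1[[i]], params)
  ps <- if (n > 1) switch_prob(diff(pos), params$recomb_rate) else numeric(0)
  # guard against exactly-zero switch probability in log space
  ps <- pmin(pmax(ps, 1e-300), 1 - 1e-16)

  # Viterbi in log space
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(0L, n, 2)
  delta[1, ] <- log(0.5) + em[1, ]
  if (n > 1) {
    for (i in 2:n) {
      lstay <- log(1 - ps[[i - 1]])
      lsw <- log(ps[[i - 1]])
      for (s in 1:2) {
        cand <- delta[i - 1, ] + c(if (s == 1) lstay else lsw,
                                   if (s == 2) lstay else lsw)
        psi[i, s] <- which.max(cand)
        delta[i, s] <- cand[[psi[i, s]]] + em[i, s]
      }
    }
  }
  path <- integer(n)
  path[[n]] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[[i]] <- psi[i + 1, path[[i + 1]]]

  # forward-backward with scaling
  fwd <- matrix(0, n, 2)
  scale <- numeric(n)
  f <- 0.5 * exp(em[1, ] - max(em[1, ]))
  scale[[1]] <- sum(f)
  fwd[1, ] <- f / scale[[1]]
  if (n > 1) {
    for (i in 2:n) {
      tr <- matrix(c(1 - ps[[i - 1]], ps[[i - 1]], ps[[i - 1]], 1 - ps[[i - 1]]), 2, 2)
      f <- (fwd[i - 1, ] %*% tr) * exp(em[i, ] - max(em[i, ]))
      scale[[i]] <- sum(f)
      fwd[i, ] <- f / scale[[i]]
    }
  }
  bwd <- matrix(0, n, 2)
  bwd[n, ] <- 1
  if (n > 1) {
    for (i in (n - 1):1) {
      tr <- matrix(c(1 - ps[[i]], ps[[i]], ps[[i]], 1 - ps[[i]]), 2, 2)
      b <- tr %*% (exp(em[i + 1, ] - max(em[i + 1, ])) * bwd[i + 1, ])
      bwd[i, ] <- b / sum(b)
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)

  tibble::tibble(pos = pos, obs = obs, state = path - 1L,
                 post0 = post[, 1], post1 = post[, 2])
}
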