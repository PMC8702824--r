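# Independent oracles used to cross-check the package's implementations.
# They are written in a different style from the production code (requirement
# tables, exhaustive enumeration) so that agreement is informative.

# --- ACMG combining-rule oracle ---------------------------------------------
# Each rule is a minimal requirement vector; a side fires when the observed
# counts dominate (>=) any requirement of that side.
oracle_acmg <- function(k) {
  dominates <- function(req) all(unlist(k)[names(req)] >= req)
  fires <- function(reqs) any(vapply(reqs, dominates, logical(1)))
  path_reqs <- list(
    c(p_vs = 1, p_s = 1), c(p_vs = 1, p_m = 2), c(p_vs = 1, p_m = 1, p_p = 1),
    c(p_vs = 1, p_p = 2),
    c(p_s = 2),
    c(p_s = 1, p_m = 3), c(p_s = 1, p_m = 2, p_p = 2), c(p_s = 1, p_m = 1, p_p = 4)
  )
  lp_reqs <- list(
    c(p_vs = 1, p_m = 1),
    c(p_s = 1, p_m = 1), c(p_s = 1, p_p = 2),
    c(p_m = 3), c(p_m = 2, p_p = 2), c(p_m = 1, p_p = 4)
  )
  ben_reqs <- list(c(b_sa = 1), c(b_s = 2))
  lb_reqs <- list(c(b_s = 1, b_p = 1), c(b_p = 2))

  p_fire <- fires(path_reqs)
  lp_fire <- fires(lp_reqs)
  b_fire <- fires(ben_reqs)
  lb_fire <- fires(lb_reqs)
  path_side <- p_fire || lp_fire
  ben_side <- b_fire || lb_fire
  if (path_side && ben_side) return("uncertain_significance")
  if (p_fire) return("pathogenic")
  if (lp_fire) return("likely_pathogenic")
  if (b_fire) return("benign")
  if (lb_fire) return("likely_benign")
  "uncertain_significance"
}

# Build an evidence set realizing the given per-strength counts, using
# distinct codes with explicit strength suffixes.
evidence_from_counts <- function(p_vs = 0, p_s = 0, p_m = 0, p_p = 0,
                                 b_sa = 0, b_s = 0, b_p = 0) {
  p_pool <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
  b_pool <- c(paste0("BS", 1:4), paste0("BP", 1:7))
  toks <- character(0)
  take_p <- function(n, strength) {
    used <- length(toks[!startsWith(toks, "B")])
    codes <- p_pool[(used + 1):(used + n)]
    paste0(codes, "_", strength)
  }
  if (p_vs > 0) toks <- c(toks, take_p(p_vs, "VeryStrong"))
  if (p_s > 0) toks <- c(toks, take_p(p_s, "Strong"))
  if (p_m > 0) toks <- c(toks, take_p(p_m, "Moderate"))
  if (p_p > 0) toks <- c(toks, take_p(p_p, "Supporting"))
  if (b_sa > 0) toks <- c(toks, "BA1")
  n_b <- 0
  if (b_s > 0) {
    toks <- c(toks, paste0(b_pool[(n_b + 1):(n_b + b_s)], "_Strong")); n_b <- n_b + b_s
  }
  if (b_p > 0) {
    toks <- c(toks, paste0(b_pool[(n_b + 1):(n_b + b_p)], "_Supporting"))
  }
  parse_evidence(toks)
}

# --- Viterbi exhaustive oracle ----------------------------------------------
hmm_path_logp <- function(path, obs, hap0, hap1, pos, params) {
  n <- length(obs)
  lp <- log(0.5)
  for (i in seq_len(n)) {
    a <- if (path[[i]] == 0L) hap0[[i]] else hap1[[i]]
    ado <- params$ado_rate
    err <- params$geno_error
    p_na <- (ado + ado^2) / 2
    p_wrong <- ado * (1 - ado) / 2 + (1 - ado)^2 * err
    e <- if (is.na(obs[[i]])) {
      max(p_na, 1e-12)
    } else if (obs[[i]] == a) {
      max(1 - p_na - p_wrong, 1e-12)
    } else {
      max(p_wrong, 1e-12)
    }
    lp <- lp + log(e)
    if (i > 1) {
      d <- pos[[i]] - pos[[i - 1]]
      psw <- (1 - exp(-2 * params$recomb_rate * d)) / 2
      psw <- min(max(psw, 1e-300), 1 - 1e-16)
      lp <- lp + log(if (path[[i]] != path[[i - 1]]) psw else 1 - psw)
    }
  }
  lp
}

oracle_viterbi_logp <- function(obs, hap0, hap1, pos, params) {
  n <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  max(apply(grid, 1, hmm_path_logp, obs = obs, hap0 = hap0, hap1 = hap1,
            pos = pos, params = params))
}

# --- co-segregation likelihood-ratio oracle ---------------------------------
# Fully penetrant dominant model, zero recombination: probability under the
# no-linkage null that all m observed meioses transmit the variant exactly as
# observed, by enumeration of all 2^m transmission patterns.
oracle_coseg_lr <- function(m) {
  if (m == 0) return(1)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  p_null <- mean(apply(grid, 1, function(g) all(g == 1L)))
  1 / p_null
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- small direct constructors ----------------------------------------------
# tiny genotype matrix from explicit dosage rows (markers x samples)
make_gm <- function(dosage, pos = NULL, roles = NULL, chrom = "15") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  pos <- pos %||% seq(10000L, by = 10000L, length.out = n)
  samples <- tibble::tibble(
    sample = colnames(dosage),
    role = roles %||% rep("other", ncol(dosage))
  )
  genotype_matrix(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   id = paste0("m", seq_len(n)), ref = "A", alt = "G"),
    dosage, samples
  )
}
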