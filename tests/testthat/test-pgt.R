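# helpers ---------------------------------------------------------------

# noise-free family: carrier parent het everywhere, other parent hom ref,
# carrier hap0 = all alt allele (1), hap1 = all ref (0); a carrier child is
# the phase reference.
simple_family <- function(n = 10, embryo_dosage = NULL) {
  dos <- cbind(
    carrier = rep(1L, n),
    other = rep(0L, n),
    refchild = rep(1L, n), # inherited hap0 (alt) from carrier + ref from other
    embryo = embryo_dosage %||% rep(0L, n)
  )
  make_gm(dos, roles = c("carrier_parent", "other_parent",
                         "reference_relative", "embryo"))
}

test_that("informative markers require carrier het, other parent hom, window", {
  gm <- make_gm(cbind(carrier = c(1L, 0L, 1L, 2L, 1L, NA),
                      other = c(0L, 0L, 1L, 0L, 2L, 0L)),
                roles = c("carrier_parent", "other_parent"))
  mask <- select_informative(gm)
  expect_equal(mask, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # window filter
  mask_w <- select_informative(gm, window = c(1, 15000))
  expect_equal(which(mask_w), 1L)
  # no informative markers warns
  gm0 <- make_gm(cbind(carrier = c(0L, 0L), other = c(0L, 0L)),
                 roles = c("carrier_parent", "other_parent"))
  expect_warning(select_informative(gm0), "no informative markers")
})

test_that("phasing against a carrier child recovers the disease haplotype exactly", {
  gm <- simple_family(n = 8)
  mask <- select_informative(gm)
  expect_true(all(mask))
  ph <- phase_parent(gm, mask, reference_status = "carrier",
                     reference_relation = "child")
  expect_equal(ph$hap0, rep(1L, 8))
  expect_equal(ph$hap1, rep(0L, 8))
  # a non-carrier reference flips the assignment
  ph2 <- phase_parent(gm, mask, reference_status = "non_carrier",
                      reference_relation = "child")
  expect_equal(ph2$hap0, rep(0L, 8))
})

test_that("phasing against a homozygous grandparent drops ambiguous markers", {
  dos <- cbind(carrier = rep(1L, 4),
               other = rep(0L, 4),
               gp = c(2L, 0L, 1L, NA)) # hom-alt, hom-ref, het (ambiguous), missing
  gm <- make_gm(dos, roles = c("carrier_parent", "other_parent", "reference_relative"))
  mask <- select_informative(gm)
  ph <- phase_parent(gm, mask, reference_status = "carrier",
                     reference_relation = "parent")
  expect_equal(ph$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ph$hap0[1:2], c(1L, 0L))
  # reference untyped everywhere -> phasing error
  dos2 <- dos; dos2[, "gp"] <- NA_integer_
  gm2 <- make_gm(dos2, roles = c("carrier_parent", "other_parent", "reference_relative"))
  expect_error(phase_parent(gm2, select_informative(gm2),
                            reference_relation = "parent"),
               "untyped or ambiguous")
})

test_that("support counts split cleanly for noise-free carrier and non-carrier embryos", {
  n <- 35
  # non-carrier embryo: inherited hap1 (ref) from carrier
  gm <- simple_family(n, embryo_dosage = rep(0L, n))
  ph <- phase_parent(gm, select_informative(gm))
  sup <- embryo_support_counts(gm, "embryo", ph)
  expect_equal(c(sup$support0, sup$support1), c(0L, 35L))
  # carrier embryo mirror case
  gm2 <- simple_family(n, embryo_dosage = rep(1L, n))
  sup2 <- embryo_support_counts(gm2, "embryo", phase_parent(gm2, select_informative(gm2)))
  expect_equal(c(sup2$support0, sup2$support1), c(35L, 0L))
  # missing sites support neither
  gm3 <- simple_family(10, embryo_dosage = c(rep(0L, 7), NA, NA, 2L))
  sup3 <- embryo_support_counts(gm3, "embryo", phase_parent(gm3, select_informative(gm3)))
  expect_equal(sup3$support0 + sup3$support1, 7L)
})

test_that("majority verdicts follow the larger count with ties as no_call", {
  expect_equal(call_from_counts(c(0, 32, 1, 0), c(35, 0, 26, 0)),
               c("non_carrier", "carrier", "non_carrier", "no_call"))
})

test_that("Viterbi matches the exhaustive path enumeration oracle on small instances", {
  set.seed(91)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    pos <- sort(sample(1:1000000, n))
    hap0 <- sample(0:1, n, replace = TRUE)
    hap1 <- 1L - hap0
    params <- hmm_params(ado_rate = runif(1, 0, 0.3),
                         geno_error = runif(1, 0.001, 0.05),
                         recomb_rate = 10^runif(1, -9, -7))
    obs <- ifelse(runif(n) < params$ado_rate, NA_integer_,
                  ifelse(runif(n) < 0.5, hap0, hap1))
    dec <- hmm_decode(obs, hap0, hap1, pos, params)
    engine_lp <- hmm_path_logp(dec$state, obs, hap0, hap1, pos, params)
    oracle_lp <- oracle_viterbi_logp(obs, hap0, hap1, pos, params)
    expect_equal(engine_lp, oracle_lp, tolerance = 1e-9)
  }
})

test_that("decoding posteriors are calibrated at the single-marker and noise-free limits", {
  params <- hmm_params(ado_rate = 0, geno_error = 0.01)
  one <- hmm_decode(0L, hap0 = 0L, hap1 = 1L, pos = 500000L, params)
  expect_equal(one$state, 0L)
  expect_gte(one$post0, 1 - 0.02)
  # empty input decodes to an empty path
  empty <- hmm_decode(integer(0), integer(0), integer(0), integer(0), params)
  expect_equal(nrow(empty), 0L)
})

test_that("hap0/hap1 label swap inverts verdicts and swaps support counts", {
  set.seed(17)
  n <- 30
  pos <- sort(sample(1:1000000, n))
  hap0 <- sample(0:1, n, replace = TRUE)
  hap1 <- 1L - hap0
  obs <- ifelse(runif(n) < 0.1, NA_integer_, ifelse(runif(n) < 0.8, hap0, hap1))
  params <- hmm_params()
  gene <- c(400000, 600000)
  d1 <- hmm_decode(obs, hap0, hap1, pos, params)
  d2 <- hmm_decode(obs, hap1, hap0, pos, params)
  s1 <- list(support0 = sum(obs == hap0, na.rm = TRUE),
             support1 = sum(obs == hap1, na.rm = TRUE), obs = obs)
  s2 <- list(support0 = s1$support1, support1 = s1$support0, obs = obs)
  c1 <- call_embryo(d1, s1, gene, params)
  c2 <- call_embryo(d2, s2, gene, params)
  expect_equal(d2$state, 1L - d1$state)
  expect_equal(c2$support0, c1$support1)
  flip <- c(carrier = "non_carrier", non_carrier = "carrier", no_call = "no_call")
  expect_equal(c2$verdict, unname(flip[c1$verdict]))
})

test_that("decoding depends only on inter-marker distances, not absolute coordinates", {
  set.seed(23)
  n <- 20
  pos <- sort(sample(1:500000, n))
  hap0 <- sample(0:1, n, replace = TRUE)
  hap1 <- 1L - hap0
  obs <- ifelse(runif(n) < 0.15, NA_integer_, ifelse(runif(n) < 0.85, hap0, hap1))
  params <- hmm_params()
  a <- hmm_decode(obs, hap0, hap1, pos, params)
  b <- hmm_decode(obs, hap0, hap1, pos + 1234567L, params)
  expect_equal(a$state, b$state)
  expect_equal(a$post0, b$post0)
})

test_that("with no noise and no recombination the HMM and majority rule agree", {
  cfg <- sim_config(template = "fam5", n_markers = 120, n_embryos = 6,
                    recomb_rate = 0, ado_rate = 0, geno_error = 0, seed = 5)
  fam <- simulate_embryos(simulate_family(cfg))
  hmm <- pgt_analyse(fam$gm, gene = cfg$gene, reference_relation = "parent",
                     params = hmm_params(ado_rate = 0, geno_error = 0, recomb_rate = 0))
  maj <- pgt_analyse(fam$gm, gene = cfg$gene, reference_relation = "parent",
                     method = "majority",
                     params = hmm_params(ado_rate = 0, geno_error = 0, recomb_rate = 0))
  expect_equal(hmm$calls$verdict, maj$calls$verdict)
  # and both match simulated truth exactly
  truth <- vapply(fam$truth$embryos, function(e) e$carrier_status, logical(1))
  expect_equal(hmm$calls$verdict,
               unname(ifelse(truth[hmm$calls$embryo], "carrier", "non_carrier")))
})

test_that("support-count attrition under allele dropout matches its expectation", {
  # per informative site, the observation is lost when both alleles drop
  # (ado^2) or when the non-transmitted-side allele of a het site survives
  # alone; het sites occur at rate 1/2, giving loss = (ado + ado^2) / 2
  ado <- 0.2
  set.seed(41)
  n <- 40
  reps <- 1000
  lost <- numeric(reps)
  gm0 <- simple_family(n)
  ph <- phase_parent(gm0, select_informative(gm0))
  for (r in seq_len(reps)) {
    # true embryo: inherits hap1 (allele 0) from carrier; other parent gives 0;
    # half the sites are made het by flipping the carrier-side transmission
    trans <- sample(0:1, n, replace = TRUE)
    true_dos <- trans # other parent contributes ref (0)
    obs_dos <- vapply(seq_len(n), function(i) {
      alleles <- c(trans[[i]], 0L)
      dropped <- runif(2) < ado
      if (all(dropped)) return(NA_integer_)
      if (any(dropped)) return(2L * alleles[[which(!dropped)]])
      sum(alleles)
    }, integer(1))
    gm <- simple_family(n, embryo_dosage = obs_dos)
    sup <- embryo_support_counts(gm, "embryo", ph)
    lost[[r]] <- n - (sup$support0 + sup$support1)
  }
  expected_loss <- n * (ado + ado^2) / 2
  se <- sd(lost) / sqrt(reps)
  expect_lt(abs(mean(lost) - expected_loss), 4 * se + 0.2)
  expect_true(all(lost >= 0))
})

test_that("a recombination event outside the gene interval never changes the verdict", {
  set.seed(67)
  params <- hmm_params(ado_rate = 0.05, geno_error = 0.005)
  gene <- c(400000, 600000)
  n <- 40
  for (rep in 1:25) {
    pos <- sort(sample(1:1000000, n))
    hap0 <- sample(0:1, n, replace = TRUE)
    hap1 <- 1L - hap0
    # crossover strictly outside the gene: in (0, 350kb) or (650kb, 1Mb)
    xo <- if (rep %% 2) runif(1, 1, 350000) else runif(1, 650000, 1000000)
    true_state <- as.integer(pos > xo)
    if (rep %% 2 == 0) true_state <- 1L - true_state # switch away from gene side
    # ensure the state at the gene is defined by truth without the crossover
    obs <- ifelse(runif(n) < params$ado_rate, NA_integer_,
                  ifelse(true_state == 0L, hap0, hap1))
    base_state <- unique(true_state[pos >= gene[[1]] & pos <= gene[[2]]])
    dec <- hmm_decode(obs, hap0, hap1, pos, params)
    sup <- list(support0 = sum(obs == hap0, na.rm = TRUE),
                support1 = sum(obs == hap1, na.rm = TRUE), obs = obs)
    verdict <- call_embryo(dec, sup, gene, params)$verdict
    # verdict must reflect the state at the gene, crossover notwithstanding
    expect_equal(verdict, if (identical(base_state, 0L)) "carrier" else "non_carrier")
  }
})

test_that("the full analysis assembles verdicts, reports and plots", {
  cfg <- sim_config(template = "fam5", n_markers = 200, n_embryos = 8, seed = 12)
  fam <- simulate_embryos(simulate_family(cfg))
  an <- pgt_analyse(fam$gm, gene = cfg$gene, reference_relation = "parent")
  expect_s3_class(an, "pgt_analysis")
  expect_equal(nrow(tidy(an)), 8L)
  rep <- pgt_report(an)
  expect_equal(rep$summary$n_carrier + rep$summary$n_non_carrier +
                 rep$summary$n_no_call, 8L)
  g <- glance(an)
  expect_gte(g$n_informative, 1L)
  p <- autoplot(an)
  expect_s3_class(p, "ggplot")
})
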