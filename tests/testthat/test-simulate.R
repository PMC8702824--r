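# Independent Mendelian-consistency check: a child's (pre-noise) genotype at
# every marker must be expressible as one allele from each parent.
mendelian_consistent <- function(child_dos, father_dos, mother_dos) {
  ok <- logical(length(child_dos))
  for (i in seq_along(child_dos)) {
    fa <- switch(father_dos[[i]] + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    mo <- switch(mother_dos[[i]] + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    ok[[i]] <- any(outer(fa, mo, `+`) == child_dos[[i]])
  }
  all(ok)
}

test_that("simulation is reproducible from its single seed", {
  cfg <- sim_config(template = "fam8", n_markers = 80, n_embryos = 4, seed = 99)
  a <- simulate_embryos(simulate_family(cfg))
  b <- simulate_embryos(simulate_family(sim_config(template = "fam8", n_markers = 80,
                                                   n_embryos = 4, seed = 99)))
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$truth$embryos, b$truth$embryos)
  # different seed differs
  c <- simulate_embryos(simulate_family(sim_config(template = "fam8", n_markers = 80,
                                                   n_embryos = 4, seed = 100)))
  expect_false(identical(a$gm$dosage, c$gm$dosage))
})

test_that("founder allele frequencies match the configured MAF", {
  # 10,000 founder haplotypes at maf 0.3
  set.seed(3)
  x <- rbinom(10000, 1, 0.3)
  expect_lt(abs(mean(x) - 0.3), 0.015)
  # and within the simulator: founder alt dosage mean ~ 2*maf per marker
  cfg <- sim_config(template = "fam8", n_markers = 400,
                    maf_range = c(0.3, 0.3), n_embryos = 1, seed = 8)
  fam <- simulate_family(cfg)
  founder_mean <- mean(fam$gm$dosage[, c("father", "mother")]) / 2
  expect_lt(abs(founder_mean - 0.3), 0.03)
})

test_that("generated families are Mendelian-consistent before noise", {
  for (seed in 1:5) {
    cfg <- sim_config(template = "fam5", n_markers = 60, n_embryos = 4, seed = seed)
    fam <- simulate_embryos(simulate_family(cfg))
    d <- fam$gm$dosage
    expect_true(mendelian_consistent(d[, "mother"], d[, "grandfather"], d[, "grandmother"]))
    for (e in names(fam$truth$embryos)) {
      expect_true(mendelian_consistent(fam$truth$embryos[[e]]$true_dosage,
                                       d[, "father"], d[, "mother"]))
    }
  }
})

test_that("disease-haplotype descent defines carrier status consistently", {
  # three-generation template: every simulated member's carrier flag agrees
  # with descent of the disease haplotype at the locus
  n_ok <- 0L
  reps <- 100L
  for (seed in seq_len(reps)) {
    fam <- simulate_family(sim_config(template = "pedigree", n_markers = 30,
                                      n_embryos = 0, seed = seed))
    ped <- fam$pedigree
    carrier_flags <- setNames(ped$carrier == "carrier", ped$id)
    truth_flags <- vapply(names(fam$truth$carrier_hap),
                          function(id) fam$truth$carrier_hap[[id]] != 0, logical(1))
    if (all(carrier_flags[names(truth_flags)] == truth_flags)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, reps)
})

test_that("no recombination means zero crossovers; zero noise means exact Mendelian dosages", {
  cfg <- sim_config(template = "fam8", n_markers = 50, n_embryos = 6,
                    recomb_rate = 0, ado_rate = 0, geno_error = 0, seed = 21)
  fam <- simulate_embryos(simulate_family(cfg))
  for (e in fam$truth$embryos) {
    expect_equal(length(e$crossovers_carrier) + length(e$crossovers_other), 0L)
  }
  emb <- grep("^embryo_", colnames(fam$gm$dosage), value = TRUE)
  for (e in emb) {
    expect_equal(fam$gm$dosage[, e], fam$truth$embryos[[e]]$true_dosage,
                 ignore_attr = TRUE)
  }
})

test_that("crossover counts follow the Poisson expectation of the genetic map", {
  # r = 1e-8 per bp over ~1 Mb: ~0.01 expected crossovers per gamete,
  # 0.02 per diploid transmission; check the mean over 10,000 meioses
  cfg <- sim_config(template = "fam8", n_markers = 10, n_embryos = 5000, seed = 55)
  fam <- simulate_embryos(simulate_family(cfg))
  n_xo <- vapply(fam$truth$embryos,
                 function(e) length(e$crossovers_carrier) + length(e$crossovers_other),
                 numeric(1))
  lambda <- 2 * 1e-8 * (1000000 - 1 + 1)
  total <- sum(n_xo)
  # Poisson total over 5000 embryos: mean 100, sd 10
  expect_lt(abs(total - 5000 * lambda), 4 * sqrt(5000 * lambda))
})

test_that("fixtures round-trip through the VCF/PED writers and readers", {
  cfg <- sim_config(template = "fam5", n_markers = 40, n_embryos = 3, seed = 77)
  fam <- simulate_embryos(simulate_family(cfg))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(fam, dir)
  expect_true(all(file.exists(unlist(paths))))

  gm2 <- read_genotypes(file.path(dir, "family.vcf"))
  expect_identical(gm2$dosage[, colnames(fam$gm$dosage)], fam$gm$dosage)
  expect_identical(as.data.frame(gm2$markers), as.data.frame(fam$gm$markers))

  ped2 <- read_ped(file.path(dir, "family.ped"))
  expect_equal(sort(ped2$id), sort(fam$pedigree$id))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 77L)
  for (e in truth$embryos) {
    expect_false(is.unsorted(e$crossovers_carrier))
  }
})

test_that("a Table-4-scale scenario yields support counts of the printed magnitude", {
  # tune the panel so roughly 35 markers are informative after phasing, then
  # check clean embryos produce lopsided counts like the published rows
  cfg <- sim_config(template = "fam8", n_markers = 160, n_embryos = 8,
                    ado_rate = 0.05, geno_error = 0.005, seed = 13)
  fam <- simulate_embryos(simulate_family(cfg))
  carrier_emb <- names(Filter(function(e) e$carrier_status, fam$truth$embryos))[[1]]
  fam$gm$samples$role[fam$gm$samples$sample == carrier_emb] <- "reference_relative"
  an <- pgt_analyse(fam$gm, gene = cfg$gene, reference_relation = "child",
                    reference_status = "carrier")
  expect_gte(glance(an)$n_informative, 20L)
  sup <- tidy(an)
  dominant <- pmax(sup$support0, sup$support1)
  minority <- pmin(sup$support0, sup$support1)
  expect_true(all(dominant >= 10))
  expect_true(all(minority <= 0.2 * dominant))
})
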