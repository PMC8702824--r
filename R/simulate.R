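# Synthetic family / embryo generator.
#
# Emulates the data a PGT-M probe panel produces: biallelic SNP markers in a
# 1 Mb window around a fictive 240 kb disease gene, a nuclear or extended
# family segregating one autosomal-dominant variant, Mendelian transmission
# with Haldane (no-interference) recombination, and MDA artifacts in the
# embryo genotypes (per-allele dropout with the surviving-allele convention,
# plus random allele flips). Markers are drawn independently (no LD); all
# randomness flows from the single seed in the config.

#' Simulation configuration
#'
#' @param template Pedigree template: `"fam5"` (three-generation maternal
#'   carrier lineage: the carrier parent's parents, the couple, embryos),
#'   `"fam8"` (carrier father and non-carrier mother only; a carrier embryo
#'   serves as phase reference), or `"pedigree"` (single-variant
#'   autosomal-dominant segregation family for co-segregation analyses).
#' @param n_markers Number of SNP markers in the window.
#' @param window Length-2 integer window (bp); default `c(1, 1000000)`.
#' @param gene Length-2 integer gene span inside the window; default a 240 kb
#'   gene centred in the window.
#' @param chrom Chromosome label for output files.
#' @param maf_range Range of the uniform minor-allele-frequency distribution;
#'   default `c(0.1, 0.5)`.
#' @param n_embryos Number of embryos; default 8.
#' @param recomb_rate Per-bp crossover probability; default 1e-8.
#' @param ado_rate,geno_error MDA noise rates applied to embryo genotypes;
#'   defaults 0.10 and 0.01.
#' @param seed Integer seed; required — every source of randomness flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(template = c("fam5", "fam8", "pedigree"),
                       n_markers = 200, window = c(1L, 1000000L),
                       gene = NULL, chrom = "15",
                       maf_range = c(0.1, 0.5), n_embryos = 8,
                       recomb_rate = 1e-8, ado_rate = 0.10, geno_error = 0.01,
                       seed) {
  template <- match.arg(template)
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  if (is.null(gene)) {
    mid <- (window[[1]] + window[[2]]) / 2
    gene <- c(as.integer(mid - 120000), as.integer(mid + 120000))
  }
  stopifnot(n_markers >= 1, gene[[1]] >= window[[1]], gene[[2]] <= window[[2]],
            ado_rate >= 0, ado_rate < 1, geno_error >= 0, geno_error < 1)
  structure(list(template = template, n_markers = as.integer(n_markers),
                 window = as.integer(window), gene = as.integer(gene),
                 chrom = chrom, maf_range = maf_range,
                 n_embryos = as.integer(n_embryos),
                 recomb_rate = recomb_rate, ado_rate = ado_rate,
                 geno_error = geno_error, seed = as.integer(seed)),
            class = "sim_config")
}

# one gamete from a pair of haplotypes (columns of a markers x 2 matrix).
# Returns the gamete, the crossover positions, and the source haplotype at
# an arbitrary query position (the disease locus).
meiosis <- function(haps, pos, window, r, query_pos) {
  L <- window[[2]] - window[[1]] + 1
  n_xo <- rpois(1, r * L)
  xo <- sort(runif(n_xo, window[[1]], window[[2]]))
  start <- sample(1:2, 1)
  source <- start
  seg <- rep(start, length(pos))
  for (x in xo) {
    flip <- pos > x
    seg[flip] <- 3L - seg[flip]
  }
  q_source <- start
  if (length(xo)) q_source <- ifelse(sum(xo < query_pos) %% 2 == 0, start, 3L - start)
  gamete <- haps[cbind(seq_along(pos), seg)]
  list(gamete = gamete, crossovers = xo, segment_source = seg, query_source = q_source)
}

draw_founder <- function(maf, n_hap = 2) {
  matrix(rbinom(length(maf) * n_hap, 1, rep(maf, n_hap)), ncol = n_hap)
}

#' Simulate a family segregating one dominant variant
#'
#' Draws founder haplotypes from per-marker allele frequencies, labels one
#' founder haplotype as disease-linked, and transmits haplotypes through the
#' pedigree template with recombination. Carrier status of a non-founder is
#' defined by descent of the disease haplotype at the gene midpoint; where a
#' template fixes an individual's carrier status (e.g. the carrier parent of
#' the couple), the meiosis is redrawn until that status is realized.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_family` with elements `gm` (a
#'   [genotype_matrix()] of the family, before embryos), `pedigree` (tibble
#'   in [read_ped()] layout), `haplotypes` (per-individual markers x 2
#'   matrices), `truth` (disease-haplotype descent and crossovers per
#'   meiosis) and the `cfg`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pos <- sort(unique(as.integer(round(runif(cfg$n_markers * 2,
                                            cfg$window[[1]], cfg$window[[2]])))))
  pos <- sort(sample(pos, min(cfg$n_markers, length(pos))))
  maf <- runif(length(pos), cfg$maf_range[[1]], cfg$maf_range[[2]])
  ref_alt <- t(vapply(seq_along(pos), function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
  markers <- tibble::tibble(chrom = cfg$chrom, pos = pos,
                            id = paste0("snp_", seq_along(pos)),
                            ref = ref_alt[, 1], alt = ref_alt[, 2])
  qpos <- mean(cfg$gene)

  haps <- list()
  carrier_of <- list() # which haplotype column (1/2) carries the variant; 0 = none
  truth <- list(crossovers = list(), maf = maf, disease_pos = qpos)

  transmit <- function(parent_id, child_label, want = NULL) {
    # one meiosis from parent; `want` forces descent (TRUE) / non-descent
    # (FALSE) of the disease haplotype at the gene midpoint, by redraw
    repeat {
      m <- meiosis(haps[[parent_id]], pos, cfg$window, cfg$recomb_rate, qpos)
      got <- carrier_of[[parent_id]] != 0 && m$query_source == carrier_of[[parent_id]]
      if (is.null(want) || got == want) {
        truth$crossovers[[paste0(parent_id, "->", child_label)]] <<- m$crossovers
        return(list(gamete = m$gamete, carries = got, source = m$segment_source,
                    parent_carrier_hap = carrier_of[[parent_id]]))
      }
    }
  }

  add_founder <- function(id, carries_variant = FALSE) {
    haps[[id]] <<- draw_founder(maf)
    carrier_of[[id]] <<- if (carries_variant) 1L else 0L
  }
  add_child <- function(id, father, mother, want_from = NULL, want = NULL) {
    pm <- transmit(mother, id, if (identical(want_from, "mother")) want else NULL)
    pf <- transmit(father, id, if (identical(want_from, "father")) want else NULL)
    haps[[id]] <<- cbind(pf$gamete, pm$gamete)
    carrier_of[[id]] <<- if (pf$carries) 1L else if (pm$carries) 2L else 0L
    # truth: which parental haplotype segment each marker came from
    truth$descent[[id]] <<- list(father = pf$source, mother = pm$source)
  }

  ped_rows <- list()
  add_ped <- function(id, father, mother, sex, affected, carrier) {
    ped_rows[[id]] <<- tibble::tibble(
      family_id = "sim", id = id,
      father_id = father, mother_id = mother, sex = sex,
      affected = affected, carrier = carrier)
  }

  if (cfg$template == "fam5") {
    # affected carrier grandfather -> affected carrier mother -> embryos
    add_founder("grandfather", carries_variant = TRUE)
    add_founder("grandmother")
    add_child("mother", "grandfather", "grandmother", want_from = "father", want = TRUE)
    add_founder("father")
    add_ped("grandfather", NA, NA, "male", "affected", "carrier")
    add_ped("grandmother", NA, NA, "female", "unaffected", "non_carrier")
    add_ped("mother", "grandfather", "grandmother", "female", "affected", "carrier")
    add_ped("father", NA, NA, "male", "unaffected", "non_carrier")
    roles <- c(mother = "carrier_parent", father = "other_parent",
               grandfather = "reference_relative", grandmother = "other")
  } else if (cfg$template == "fam8") {
    add_founder("father", carries_variant = TRUE)
    add_founder("mother")
    add_ped("father", NA, NA, "male", "affected", "carrier")
    add_ped("mother", NA, NA, "female", "unaffected", "non_carrier")
    roles <- c(father = "carrier_parent", mother = "other_parent")
  } else {
    # three-generation segregation family: founder couple, three children
    # (carrier status by descent), one grandchild
    add_founder("I-1", carries_variant = TRUE)
    add_founder("I-2")
    add_child("II-1", "I-1", "I-2")
    add_child("II-2", "I-1", "I-2", want_from = "father", want = TRUE)
    add_child("II-3", "I-1", "I-2")
    add_founder("II-4")
    add_child("III-1", "II-4", "II-2", want_from = NULL)
    status <- function(id) if (carrier_of[[id]] != 0) "carrier" else "non_carrier"
    aff <- function(id) if (carrier_of[[id]] != 0) "affected" else "unaffected"
    add_ped("I-1", NA, NA, "male", "affected", "carrier")
    add_ped("I-2", NA, NA, "female", "unaffected", "non_carrier")
    add_ped("II-1", "I-1", "I-2", "male", aff("II-1"), status("II-1"))
    add_ped("II-2", "I-1", "I-2", "female", aff("II-2"), status("II-2"))
    add_ped("II-3", "I-1", "I-2", "male", aff("II-3"), status("II-3"))
    add_ped("II-4", NA, NA, "male", "unaffected", "non_carrier")
    add_ped("III-1", "II-4", "II-2", "female", aff("III-1"), status("III-1"))
    roles <- setNames(rep("other", length(haps)), names(haps))
    roles[["II-2"]] <- "carrier_parent"
    roles[["II-4"]] <- "other_parent"
    roles[["I-1"]] <- "reference_relative"
  }

  dosage <- vapply(names(haps), function(id) as.integer(rowSums(haps[[id]])),
                   integer(length(pos)))
  samples <- tibble::tibble(sample = names(haps),
                            role = unname(roles[names(haps)]))
  gm <- genotype_matrix(markers, dosage, samples)
  truth$carrier_hap <- carrier_of
  structure(list(gm = gm, pedigree = dplyr::bind_rows(ped_rows),
                 haplotypes = haps, truth = truth, cfg = cfg),
            class = "sim_family")
}

# apply MDA noise to one diploid genotype given as a 2-vector of alleles:
# per-allele flip with prob err, then per-allele dropout with prob ado;
# one survivor -> observed homozygous for the survivor; none -> missing.
mda_noise_alleles <- function(alleles, ado, err) {
  flip <- runif(2) < err
  alleles[flip] <- 1L - alleles[flip]
  dropped <- runif(2) < ado
  if (all(dropped)) return(NA_integer_)
  if (any(dropped)) return(2L * alleles[[which(!dropped)]])
  sum(alleles)
}

#' Simulate embryo genotypes for a family
#'
#' Each embryo receives one recombined haplotype from each parent of the
#' couple; MDA noise (allele flips then per-allele dropout) is applied to the
#' observed embryo genotypes only. The truth record stores, per embryo, the
#' carrier-parent transmission track over the markers, the crossover
#' positions in both gametes, and the true carrier status.
#'
#' @param family A `sim_family` from [simulate_family()].
#' @param cfg Defaults to the family's config.
#' @return A `sim_family` with embryo columns appended to `gm` (role
#'   `embryo`) and `truth$embryos` filled: per embryo, `carrier_status`,
#'   `carrier_path` (1 = disease haplotype transmitted, coded as state 0
#'   downstream), and crossover positions per gamete.
#' @export
simulate_embryos <- function(family, cfg = family$cfg) {
  stopifnot(inherits(family, "sim_family"))
  gm <- family$gm
  pos <- gm$markers$pos
  qpos <- family$truth$disease_pos
  carrier <- role_sample(gm, "carrier_parent")
  other <- role_sample(gm, "other_parent")
  c_hap <- family$truth$carrier_hap[[carrier]]
  if (c_hap == 0) abort("carrier parent does not carry the variant in this simulation")

  emb_names <- paste0("embryo_", seq_len(cfg$n_embryos))
  dosage_new <- matrix(NA_integer_, nrow = length(pos), ncol = cfg$n_embryos,
                       dimnames = list(NULL, emb_names))
  truth_emb <- list()
  for (j in seq_len(cfg$n_embryos)) {
    mc <- meiosis(family$haplotypes[[carrier]], pos, cfg$window, cfg$recomb_rate, qpos)
    mo <- meiosis(family$haplotypes[[other]], pos, cfg$window, cfg$recomb_rate, qpos)
    true_geno <- cbind(mc$gamete, mo$gamete)
    obs <- vapply(seq_along(pos), function(i) {
      mda_noise_alleles(true_geno[i, ], cfg$ado_rate, cfg$geno_error)
    }, integer(1))
    dosage_new[, j] <- obs
    truth_emb[[emb_names[[j]]]] <- list(
      carrier_status = mc$query_source == c_hap,
      # state path in HMM coding: 0 = disease-linked haplotype transmitted
      state_path = as.integer(mc$segment_source != c_hap),
      crossovers_carrier = mc$crossovers,
      crossovers_other = mo$crossovers,
      true_dosage = as.integer(rowSums(true_geno))
    )
  }
  gm2 <- genotype_matrix(gm$markers,
                         cbind(gm$dosage, dosage_new),
                         dplyr::bind_rows(gm$samples,
                                          tibble::tibble(sample = emb_names,
                                                         role = "embryo")))
  family$gm <- gm2
  family$truth$embryos <- truth_emb
  family
}

#' Write simulated fixtures to disk
#'
#' Writes a plain-text VCF 4.2 (couple, relatives and embryos), a PED file,
#' and a truth JSON (crossovers sorted by position, carrier statuses, seed).
#'
#' @param family A `sim_family` (after [simulate_embryos()]).
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths, invisibly.
#' @export
write_fixtures <- function(family, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) abort(paste0("directory not writable: ", dir))
  vcf_path <- file.path(dir, "family.vcf")
  ped_path <- file.path(dir, "family.ped")
  truth_path <- file.path(dir, "truth.json")
  write_vcf(family$gm, vcf_path, source_tag = paste0("pgtlink-sim-seed", family$cfg$seed))

  ped <- family$pedigree
  sex_code <- c(male = "1", female = "2", unknown = "0")
  aff_code <- c(affected = "2", unaffected = "1", unknown = "0")
  car_code <- c(carrier = "2", non_carrier = "1", untested = "0")
  writeLines(paste(ped$family_id, ped$id,
                   ifelse(is.na(ped$father_id), "0", ped$father_id),
                   ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                   sex_code[ped$sex], aff_code[ped$affected], car_code[ped$carrier]),
             ped_path)

  emb <- family$truth$embryos %||% list()
  truth <- list(
    seed = family$cfg$seed,
    template = family$cfg$template,
    gene = family$cfg$gene,
    disease_pos = family$truth$disease_pos,
    embryos = purrr::map(emb, function(e) {
      list(carrier_status = e$carrier_status,
           crossovers_carrier = sort(e$crossovers_carrier),
           crossovers_other = sort(e$crossovers_other))
    })
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, ped = ped_path, truth = truth_path))
}
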