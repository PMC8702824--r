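# Reproducible pipeline driver.
#
# Thin orchestration over the package's stages: each subcommand reads
# plain-text inputs, writes plain-text TSV/JSON results plus a run manifest
# (inputs, package version, seed, parameters), and is deterministic for
# fixed inputs and seed. A command-line front end over this function ships
# in inst/cli/pgtlink.R.

#' Run a pipeline stage
#'
#' Subcommands:
#' \describe{
#'   \item{classify}{`evidence` TSV (`variant_key`, `evidence`) -> ACMG
#'     classifications + posteriors (`classifications.json`).}
#'   \item{coseg}{`ped` file (+ optional `family`, `mode`) -> eLOD and PP1
#'     strength per family (`cosegregation.json`).}
#'   \item{pgt}{`vcf` + `roles` + `gene` (+ `flank`, `reference_status`,
#'     `reference_relation`) -> per-embryo verdict TSV and path/recombination
#'     JSON.}
#'   \item{simulate}{simulation config fields -> VCF + PED + truth JSON
#'     fixtures.}
#' }
#'
#' @param config A named list: `subcommand`, `out` (output directory), `seed`
#'   (integer), plus subcommand-specific fields as above. A YAML or JSON file
#'   path is also accepted.
#' @return A list with the stage results and the manifest, invisibly; output
#'   files are written under `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  stopifnot(is.list(config), !is.null(config$subcommand))
  sub <- match.arg(config$subcommand, c("classify", "coseg", "pgt", "simulate"))
  out_dir <- config$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)

  for (f in intersect(c("evidence", "ped", "vcf"), names(config))) {
    if (!file.exists(config[[f]])) {
      abort(paste0("input file not found: ", config[[f]]))
    }
  }

  result <- switch(sub,
    classify = {
      ev <- readr::read_tsv(config$evidence, comment = "#", show_col_types = FALSE)
      cohort <- classify_variants(ev,
                                  prior = config$prior %||% 0.10,
                                  odds_very_strong = config$odds_very_strong %||% 350)
      report <- purrr::pmap(tidy(cohort), function(variant_key, classification,
                                                   fired_rule, posterior,
                                                   posterior_percent, n_items) {
        list(variant_key = variant_key, classification = classification,
             fired_rule = fired_rule, posterior_percent = posterior_percent)
      })
      jsonlite::write_json(report, file.path(out_dir, "classifications.json"),
                           auto_unbox = TRUE, digits = NA)
      cohort
    },
    coseg = {
      ped <- read_ped(config$ped)
      if (!is.null(config$family)) ped <- ped[ped$family_id == as.character(config$family), ]
      res <- cosegregate(ped, mode = config$mode %||% "affected_only")
      jsonlite::write_json(res, file.path(out_dir, "cosegregation.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    pgt = {
      roles <- unlist(config$roles)
      gm <- read_genotypes(config$vcf, roles = roles)
      an <- pgt_analyse(gm,
                        gene = as.numeric(unlist(config$gene)),
                        flank = config$flank %||% 350000,
                        reference_status = config$reference_status %||% "carrier",
                        reference_relation = config$reference_relation %||% "child",
                        params = hmm_params(
                          ado_rate = config$ado_rate %||% 0.10,
                          geno_error = config$geno_error %||% 0.01,
                          recomb_rate = config$recomb_rate %||% 1e-8,
                          min_posterior = config$min_posterior %||% 0.95),
                        method = config$method %||% "hmm")
      readr::write_tsv(tidy(an), file.path(out_dir, "embryo_calls.tsv"))
      jsonlite::write_json(
        purrr::imap(an$paths, function(p, e) list(
          embryo = e, path = p$state, pos = p$pos, post0 = p$post0,
          recombinations = an$calls$recombinations[[match(e, an$calls$embryo)]])),
        file.path(out_dir, "embryo_paths.json"), auto_unbox = TRUE, digits = NA)
      an
    },
    simulate = {
      cfg <- sim_config(template = config$template %||% "fam5",
                        n_markers = config$n_markers %||% 200,
                        n_embryos = config$n_embryos %||% 8,
                        ado_rate = config$ado_rate %||% 0.10,
                        geno_error = config$geno_error %||% 0.01,
                        seed = seed)
      fam <- simulate_embryos(simulate_family(cfg))
      write_fixtures(fam, out_dir)
      fam
    }
  )

  manifest <- list(
    subcommand = sub,
    seed = seed,
    package = "pgtlink",
    version = as.character(utils::packageVersion("pgtlink")),
    inputs = config[intersect(c("evidence", "ped", "vcf", "template", "family",
                                "mode", "gene", "flank", "n_markers", "n_embryos"),
                              names(config))],
    timestamp = NULL # deliberately omitted: outputs are byte-reproducible
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(result = result, manifest = manifest))
}

read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.(ya?ml)$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Render a human-readable summary report
#'
#' Combines stage results into fixed-order text sections: variant
#' classification (with the likely-pathogenic/pathogenic count), per-family
#' co-segregation, and per-family embryo verdicts.
#'
#' @param results A named list with any of `classification` (an
#'   `acmg_cohort`), `cosegregation` (tibble from [cosegregate()]), `pgt`
#'   (a `pgt_analysis` or named list of them).
#' @return Character vector of report lines (empty-report stub when nothing
#'   is supplied).
#' @export
render_report <- function(results) {
  lines <- character()
  if (!is.null(results$classification)) {
    g <- glance(results$classification)
    lines <- c(lines, "== Variant classification ==",
               paste0(g$n_lp_plus_p, " of ", g$n_variants,
                      " variants likely pathogenic/pathogenic"),
               purrr::pmap_chr(tidy(results$classification),
                               function(variant_key, classification, fired_rule,
                                        posterior, posterior_percent, n_items) {
                 sprintf("  %-16s %-24s posterior %.1f%%", variant_key,
                         classification, posterior_percent)
               }))
  }
  if (!is.null(results$cosegregation)) {
    cs <- results$cosegregation
    lines <- c(lines, "== Co-segregation ==",
               sprintf("  family %-4s m=%d eLOD=%.2f PP1=%s",
                       cs$family_id, cs$m, cs$elod, cs$pp1_strength))
  }
  if (!is.null(results$pgt)) {
    pg <- results$pgt
    if (inherits(pg, "pgt_analysis")) pg <- list(pgt = pg)
    for (nm in names(pg)) {
      s <- glance(pg[[nm]])
      lines <- c(lines, paste0("== PGT haplotype analysis: ", nm, " =="),
                 sprintf("  %d embryos: %d carrier, %d non-carrier, %d no-call",
                         s$n_embryos, s$n_carrier, s$n_non_carrier, s$n_no_call))
    }
  }
  if (!length(lines)) lines <- "(empty report)"
  lines
}
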