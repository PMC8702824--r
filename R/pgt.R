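# SNP-haplotype linkage analysis for PGT-M.
#
# Around the disease gene, markers where the carrier parent is heterozygous
# and the other parent homozygous are "informative": the embryo's genotype
# at such a marker reveals which of the carrier parent's haplotypes it
# inherited there. A reference relative of known variant status anchors
# which of the two parental haplotypes carries the disease allele (hap0);
# the embryo's transmitted-allele track is then decoded against hap0/hap1.

#' Select informative markers
#'
#' A marker is informative when it lies inside the locus window, the carrier
#' parent is heterozygous and the other parent homozygous (so the embryo's
#' transmitted carrier-parent allele is deducible). Phase resolution against
#' the reference relative happens later, in [phase_parent()], which may drop
#' further markers.
#'
#' @param gm A [genotype_matrix()].
#' @param window Length-2 numeric `c(start, end)` of the locus window (bp,
#'   inclusive); `NULL` keeps all markers.
#' @param carrier,other Sample names of the carrier and non-carrier parent;
#'   defaults taken from the `roles` column.
#' @return A logical mask along the marker axis. A warning is raised when no
#'   marker is informative.
#' @export
select_informative <- function(gm, window = NULL, carrier = NULL, other = NULL) {
  carrier <- carrier %||% role_sample(gm, "carrier_parent")
  other <- other %||% role_sample(gm, "other_parent")
  dc <- gm$dosage[, carrier]
  do <- gm$dosage[, other]
  mask <- !is.na(dc) & dc == 1L & !is.na(do) & do %in% c(0L, 2L)
  if (!is.null(window)) {
    mask <- mask & gm$markers$pos >= window[[1]] & gm$markers$pos <= window[[2]]
  }
  if (!any(mask)) {
    warn("no informative markers in the locus window; downstream calls will be no_call")
  }
  mask
}

role_sample <- function(gm, role) {
  hit <- gm$samples$sample[gm$samples$role == role]
  if (length(hit) != 1L) {
    abort(paste0("expected exactly one sample with role '", role, "', found ",
                 length(hit)))
  }
  hit
}

# transmitted carrier-parent allele of `sample` at masked markers:
# dosage(sample) - other parent's homozygous allele; values outside {0,1}
# (genotyping error / dropout artefact) and missing genotypes give NA.
transmitted_allele <- function(gm, sample, other, mask) {
  b <- gm$dosage[mask, other] / 2L
  t <- gm$dosage[mask, sample] - b
  t[!is.na(t) & !t %in% c(0, 1)] <- NA
  as.integer(t)
}

#' Phase the carrier parent against a reference relative
#'
#' Assigns, at each informative marker, the carrier-parent allele that
#' travels with the disease variant to haplotype 0 and the other allele to
#' haplotype 1, using a first-degree reference relative of known variant
#' status:
#' \itemize{
#'   \item reference is a child/embryo of the couple: its transmitted
#'     carrier-parent allele lies on hap0 if the reference is a carrier,
#'     else on hap1;
#'   \item reference is a parent of the carrier: a homozygous reference
#'     genotype identifies the allele the carrier inherited from it, which
#'     lies on hap0 if the reference is a carrier (the disease haplotype
#'     descended through that parent), else on hap1. Heterozygous reference
#'     genotypes are ambiguous.
#' }
#' Markers with missing, ambiguous or contradictory reference genotypes are
#' dropped from the mask.
#'
#' @param gm A [genotype_matrix()].
#' @param mask Logical informative mask from [select_informative()].
#' @param reference Sample name of the reference relative; default the sample
#'   with role `reference_relative`.
#' @param reference_status `"carrier"` or `"non_carrier"`.
#' @param reference_relation `"child"` (embryo or child of the couple) or
#'   `"parent"` (parent of the carrier parent).
#' @inheritParams select_informative
#' @return A list of class `phased_parent` with allele vectors `hap0`,
#'   `hap1` (NA off-mask), the refined logical `mask`, and `phase_source`.
#' @export
phase_parent <- function(gm, mask, reference = NULL,
                         reference_status = c("carrier", "non_carrier"),
                         reference_relation = c("child", "parent"),
                         carrier = NULL, other = NULL) {
  reference_status <- match.arg(reference_status)
  reference_relation <- match.arg(reference_relation)
  carrier <- carrier %||% role_sample(gm, "carrier_parent")
  other <- other %||% role_sample(gm, "other_parent")
  reference <- reference %||% role_sample(gm, "reference_relative")

  n <- nrow(gm$markers)
  hap0 <- rep(NA_integer_, n)
  hap1 <- rep(NA_integer_, n)
  idx <- which(mask)
  if (!length(idx)) abort("empty informative mask; nothing to phase")

  if (reference_relation == "child") {
    linked <- transmitted_allele(gm, reference, other, mask)
  } else {
    dref <- gm$dosage[mask, reference]
    linked <- ifelse(!is.na(dref) & dref %in% c(0L, 2L), dref / 2L, NA_integer_)
    linked <- as.integer(linked)
  }
  if (all(is.na(linked))) {
    abort("reference relative is untyped or ambiguous at every informative marker")
  }
  if (reference_status == "non_carrier") linked <- 1L - linked

  keep <- !is.na(linked)
  kept_idx <- idx[keep]
  hap0[kept_idx] <- linked[keep]
  hap1[kept_idx] <- 1L - linked[keep]
  new_mask <- rep(FALSE, n)
  new_mask[kept_idx] <- TRUE
  structure(list(hap0 = hap0, hap1 = hap1, mask = new_mask,
                 phase_source = reference, carrier = carrier, other = other),
            class = "phased_parent")
}

#' Per-haplotype informative-SNP support counts for one embryo
#'
#' At each retained informative marker with a deducible embryo genotype, the
#' embryo's carrier-parent-transmitted allele increments the support count of
#' the matching haplotype; undeducible sites (missing, or conflicting with
#' the obligate transmission) increment neither, so `support0 + support1`
#' can be less than the number of informative markers.
#'
#' @param gm A [genotype_matrix()].
#' @param embryo Embryo sample name.
#' @param phased A `phased_parent` from [phase_parent()].
#' @return A list with `support0`, `support1` and the observation vector
#'   `obs` over the retained markers.
#' @export
embryo_support_counts <- function(gm, embryo, phased) {
  obs <- transmitted_allele(gm, embryo, phased$other, phased$mask)
  h0 <- phased$hap0[phased$mask]
  h1 <- phased$hap1[phased$mask]
  list(support0 = sum(obs == h0, na.rm = TRUE),
       support1 = sum(obs == h1, na.rm = TRUE),
       obs = obs)
}

#' Verdict from support counts (majority rule)
#'
#' Fallback decision rule when HMM decoding is not used: the haplotype with
#' the larger informative-SNP support wins; ties (including 0-0) are
#' `no_call` — never an arbitrary pick.
#'
#' @param support0,support1 Integer vectors of per-haplotype support counts.
#' @return Character vector in `{"carrier","non_carrier","no_call"}`.
#' @export
#' @examples
#' call_from_counts(c(0, 32, 1), c(35, 0, 26))
call_from_counts <- function(support0, support1) {
  dplyr::case_when(
    support0 > support1 ~ "carrier",
    support1 > support0 ~ "non_carrier",
    TRUE ~ "no_call"
  )
}

# recombination intervals: state switches between adjacent retained markers.
# A crossover cannot be localized across markers whose observation is
# missing, so each interval is widened to the nearest flanking markers with
# a non-missing observation (the achievable resolution of the panel).
recombination_intervals <- function(path) {
  if (nrow(path) < 2) {
    return(tibble::tibble(interval_start_pos = integer(), interval_end_pos = integer()))
  }
  sw <- which(diff(path$state) != 0L)
  obs_idx <- which(!is.na(path$obs))
  start <- vapply(sw, function(i) {
    j <- obs_idx[obs_idx <= i]
    path$pos[if (length(j)) max(j) else 1L]
  }, numeric(1))
  end <- vapply(sw, function(i) {
    j <- obs_idx[obs_idx > i]
    path$pos[if (length(j)) min(j) else nrow(path)]
  }, numeric(1))
  tibble::tibble(interval_start_pos = as.integer(start),
                 interval_end_pos = as.integer(end))
}

#' Call one embryo from its decoded path
#'
#' The verdict is read at the disease-gene interval: over the retained
#' informative markers inside the gene span (or, if none, the two flanking
#' markers), the mean posterior of the disease-linked state must reach
#' `min_posterior` for `carrier`, of the normal state for `non_carrier`;
#' otherwise `no_call`. Recombination events are reported as the intervals
#' between adjacent retained markers where the decoded state switches.
#'
#' @param path Decoded tibble from [hmm_decode()].
#' @param support Support-count list from [embryo_support_counts()].
#' @param gene Length-2 numeric `c(start, end)` of the gene span (bp).
#' @param params An [hmm_params()].
#' @return A one-row tibble: `verdict`, `support0`, `support1`,
#'   `gene_posterior0`, `n_recombinations`, plus the recombination intervals
#'   in a list column.
#' @export
call_embryo <- function(path, support, gene, params = hmm_params()) {
  rec <- recombination_intervals(path)
  if (nrow(path) == 0L) {
    return(tibble::tibble(verdict = "no_call",
                          support0 = support$support0, support1 = support$support1,
                          gene_posterior0 = NA_real_, n_recombinations = 0L,
                          recombinations = list(rec)))
  }
  inside <- path$pos >= gene[[1]] & path$pos <= gene[[2]]
  if (any(inside)) {
    sel <- which(inside)
  } else {
    below <- which(path$pos < gene[[1]])
    above <- which(path$pos > gene[[2]])
    sel <- c(if (length(below)) max(below), if (length(above)) min(above))
  }
  p0 <- mean(path$post0[sel])
  verdict <- if (p0 >= params$min_posterior) {
    "carrier"
  } else if ((1 - p0) >= params$min_posterior) {
    "non_carrier"
  } else {
    "no_call"
  }
  tibble::tibble(verdict = verdict,
                 support0 = support$support0, support1 = support$support1,
                 gene_posterior0 = p0, n_recombinations = nrow(rec),
                 recombinations = list(rec))
}

#' End-to-end PGT haplotype analysis of a family's embryos
#'
#' Selects informative markers in the gene-centred window, phases the carrier
#' parent against the reference relative, decodes every embryo with the HMM
#' (or applies the majority rule with `method = "majority"`), and calls each
#' embryo carrier / non-carrier / no_call.
#'
#' @param gm A [genotype_matrix()] containing the couple, the reference
#'   relative and the embryos (roles set).
#' @param gene Length-2 numeric `c(start, end)` gene span (bp).
#' @param flank Window extension on each side of the gene (bp); default
#'   350000, the probe-panel design around the target gene.
#' @param params An [hmm_params()].
#' @param method `"hmm"` (default) or `"majority"`.
#' @inheritParams phase_parent
#' @return An object of class `pgt_analysis`; supports [tidy()], [glance()],
#'   [autoplot()] and [pgt_report()].
#' @export
pgt_analyse <- function(gm, gene, flank = 350000,
                        reference = NULL,
                        reference_status = c("carrier", "non_carrier"),
                        reference_relation = c("child", "parent"),
                        params = hmm_params(), method = c("hmm", "majority"),
                        carrier = NULL, other = NULL) {
  method <- match.arg(method)
  reference_status <- match.arg(reference_status)
  reference_relation <- match.arg(reference_relation)
  window <- c(gene[[1]] - flank, gene[[2]] + flank)
  mask <- select_informative(gm, window = window, carrier = carrier, other = other)
  embryos <- gm$samples$sample[gm$samples$role == "embryo"]
  reference <- reference %||% role_sample(gm, "reference_relative")
  embryos <- setdiff(embryos, reference)

  if (!any(mask)) {
    calls <- tibble::tibble(embryo = embryos, verdict = "no_call",
                            support0 = 0L, support1 = 0L,
                            gene_posterior0 = NA_real_, n_recombinations = 0L,
                            recombinations = list(tibble::tibble()))
    return(new_pgt_analysis(calls, NULL, mask, gm, gene, window, params, method, list()))
  }

  phased <- phase_parent(gm, mask, reference = reference,
                         reference_status = reference_status,
                         reference_relation = reference_relation,
                         carrier = carrier, other = other)
  paths <- list()
  calls <- purrr::map(embryos, function(e) {
    sup <- embryo_support_counts(gm, e, phased)
    pth <- hmm_decode(sup$obs, phased$hap0[phased$mask], phased$hap1[phased$mask],
                      gm$markers$pos[phased$mask], params)
    paths[[e]] <<- pth
    if (method == "hmm") {
      res <- call_embryo(pth, sup, gene, params)
    } else {
      res <- tibble::tibble(verdict = call_from_counts(sup$support0, sup$support1),
                            support0 = sup$support0, support1 = sup$support1,
                            gene_posterior0 = NA_real_,
                            n_recombinations = nrow(recombination_intervals(pth)),
                            recombinations = list(recombination_intervals(pth)))
    }
    dplyr::bind_cols(tibble::tibble(embryo = e), res)
  }) |> dplyr::bind_rows()
  new_pgt_analysis(calls, phased, phased$mask, gm, gene, window, params, method, paths)
}

new_pgt_analysis <- function(calls, phased, mask, gm, gene, window, params, method, paths) {
  structure(list(calls = calls, phased = phased, mask = mask, gm = gm,
                 gene = gene, window = window, params = params, method = method,
                 paths = paths),
            class = "pgt_analysis")
}

#' Cohort report for a PGT analysis
#'
#' @param x A `pgt_analysis` (or a calls tibble with a `verdict` column).
#' @return A list with `per_embryo` (tibble) and `summary` (counts of
#'   carrier / non-carrier / no-call embryos).
#' @export
pgt_report <- function(x) {
  calls <- if (inherits(x, "pgt_analysis")) x$calls else tibble::as_tibble(x)
  verdicts <- factor(calls$verdict, levels = c("carrier", "non_carrier", "no_call"))
  counts <- table(verdicts)
  list(per_embryo = calls,
       summary = tibble::tibble(n_embryos = nrow(calls),
                                n_carrier = unname(counts[["carrier"]]),
                                n_non_carrier = unname(counts[["non_carrier"]]),
                                n_no_call = unname(counts[["no_call"]])))
}

#' @method tidy pgt_analysis
#' @export
tidy.pgt_analysis <- function(x, ...) {
  dplyr::select(x$calls, -"recombinations")
}

#' @method glance pgt_analysis
#' @export
glance.pgt_analysis <- function(x, ...) {
  s <- pgt_report(x)$summary
  s$n_informative <- sum(x$mask)
  s$method <- x$method
  s
}

#' @method print pgt_analysis
#' @export
print.pgt_analysis <- function(x, ...) {
  s <- glance(x)
  cat("PGT haplotype analysis:", s$n_embryos, "embryos over", s$n_informative,
      "informative SNPs (", x$method, ")\n")
  cat("  carrier:", s$n_carrier, " non-carrier:", s$n_non_carrier,
      " no-call:", s$n_no_call, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @method autoplot pgt_analysis
#' @export
autoplot.pgt_analysis <- function(object, ...) {
  if (is.null(object$phased)) abort("nothing to plot: empty informative panel")
  mask_pos <- object$gm$markers$pos[object$phased$mask]
  df <- purrr::imap(object$paths, function(p, e) {
    h0 <- object$phased$hap0[object$phased$mask]
    support <- dplyr::case_when(
      is.na(p$obs) ~ "missing",
      p$obs == h0 ~ "hap0 (disease)",
      TRUE ~ "hap1 (normal)"
    )
    tibble::tibble(embryo = e, pos = p$pos, support = support)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1000, y = .data$embryo,
                                   fill = .data$support)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::annotate("rect", xmin = object$gene[[1]] / 1000, xmax = object$gene[[2]] / 1000,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::scale_fill_manual(values = c("hap0 (disease)" = "#d73027",
                                          "hap1 (normal)" = "#4575b4",
                                          "missing" = "grey80")) +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "supported haplotype") +
    ggplot2::theme_minimal()
}
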