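# Protein-domain annotation for fibrillin-1 variants.
#
# Fibrillin-1 (2871 aa) is a modular protein dominated by EGF-like repeats,
# most of them calcium-binding (cbEGF). Each cbEGF module carries six
# conserved cysteines forming three disulfide bonds; substitutions of those
# cysteines are a classic pathogenic mechanism in Marfan syndrome. The
# packaged table is a coarse, synthetic domain map (see the file header)
# sufficient to label the residues handled by this package.

FBN1_PROTEIN_LENGTH <- 2871L

#' Load a protein-domain interval table
#'
#' Reads a TSV with columns `domain_label`, `start`, `end` (1-based, inclusive
#' residue intervals, `#` comment header allowed). Without a `path`, the
#' packaged synthetic fibrillin-1 map is used.
#'
#' @param path Optional path to a domain table TSV.
#' @return A tibble with columns `domain_label`, `start`, `end`, sorted by
#'   `start`, with non-overlap validated.
#' @export
#' @examples
#' fbn1_domains()
fbn1_domains <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fbn1_domains_synthetic.tsv",
                                package = "pgtlink", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           domain_label = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer()
                         ))
  tbl <- dplyr::arrange(tbl, .data$start)
  if (any(tbl$end < tbl$start)) abort("domain table has an interval with end < start")
  if (nrow(tbl) > 1 && any(tbl$start[-1] <= tbl$end[-nrow(tbl)])) {
    abort("domain table intervals overlap")
  }
  tbl
}

lookup_domain <- function(pos, domains) {
  hit <- which(domains$start <= pos & domains$end >= pos)
  if (length(hit)) domains$domain_label[[hit[[1]]]] else "other"
}

#' Annotate variants with protein-domain membership
#'
#' Sets `domain_label` for each variant: splice-site variants are labelled
#' `"intronic"`; variants with a protein position are looked up in the domain
#' interval table (`"other"` when the residue falls between annotated
#' domains).
#'
#' @param variants A tibble from [parse_hgvs()] / [parse_variants()].
#' @param domains A domain table from [fbn1_domains()].
#' @param protein_length Length of the protein; positions beyond it are an
#'   error.
#' @return `variants` with `domain_label` filled in.
#' @export
annotate_domains <- function(variants, domains = fbn1_domains(),
                             protein_length = FBN1_PROTEIN_LENGTH) {
  stopifnot(is.data.frame(variants))
  lab <- variants$domain_label
  for (i in seq_len(nrow(variants))) {
    if (identical(variants$consequence[[i]], "splice_site")) {
      lab[[i]] <- "intronic"
      next
    }
    pos <- variants$protein_position[[i]]
    if (is.na(pos)) {
      abort(paste0("variant ", variants$hgvs_c[[i]],
                   " has no protein position and is not a splice-site variant"))
    }
    if (pos > protein_length || pos < 1L) {
      abort(paste0("protein position ", pos, " outside 1..", protein_length,
                   " for ", variants$hgvs_c[[i]]))
    }
    lab[[i]] <- lookup_domain(pos, domains)
  }
  variants$domain_label <- lab
  variants
}

#' Tabulate molecular consequences across a variant cohort
#'
#' Counts variants per consequence class and, among missense variants, how
#' many substitute a reference cysteine — the accounting used to describe a
#' fibrillin-1 variant spectrum, where cysteine substitutions in cbEGF
#' modules are over-represented.
#'
#' @param variants A nonempty variant tibble from [parse_variants()].
#' @return A list with `by_consequence` (tibble `consequence`, `n`, all seven
#'   classes present with zero counts where empty) and `n_cys_missense`.
#' @export
tabulate_consequences <- function(variants) {
  stopifnot(is.data.frame(variants), nrow(variants) > 0)
  counts <- variants |>
    dplyr::count(consequence = factor(.data$consequence, levels = CONSEQUENCE_LEVELS),
                 .drop = FALSE) |>
    dplyr::mutate(consequence = as.character(.data$consequence)) |>
    tibble::as_tibble()
  n_cys <- sum(variants$consequence == "missense" &
                 !is.na(variants$ref_residue) & variants$ref_residue == "Cys")
  list(by_consequence = counts, n_cys_missense = n_cys)
}
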