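# Co-segregation scoring.
#
# Under a fully penetrant autosomal-dominant model with zero recombination
# between marker and disease locus, each informative meiosis in which the
# variant travels with the phenotype multiplies the segregation likelihood
# ratio by 2, so m informative meioses give eLOD = m * log10(2) ~ 0.301 * m.
# The eLOD feeds back into ACMG classification as the applied strength of
# the PP1 (co-segregation) criterion.

#' Read pedigrees from a PED file
#'
#' Parses the 6-column linkage PED dialect (family, individual, father,
#' mother, sex, affected status) with an optional 7th column carrying variant
#' carrier status (2 = carrier, 1 = non-carrier, 0 = untested). `"0"` parents
#' are founder marks.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A tibble with one row per individual and columns `family_id`,
#'   `id`, `father_id`, `mother_id` (`NA` for founders), `sex`
#'   (male/female/unknown), `affected` (affected/unaffected/unknown) and
#'   `carrier` (carrier/non_carrier/untested).
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(family_id = character(), id = character(),
                          father_id = character(), mother_id = character(),
                          sex = character(), affected = character(),
                          carrier = character()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- vapply(fields, length, integer(1))
  bad <- which(!ncol %in% c(6L, 7L))
  if (length(bad)) {
    abort(paste0("malformed PED row at line ", bad[[1]], ": expected 6 or 7 fields, got ",
                 ncol[[bad[[1]]]]))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    tibble::tibble(
      family_id = f[[1]], id = f[[2]],
      father_id = if (f[[3]] == "0") NA_character_ else f[[3]],
      mother_id = if (f[[4]] == "0") NA_character_ else f[[4]],
      sex = c("1" = "male", "2" = "female")[f[[5]]] %|NA|% "unknown",
      affected = c("2" = "affected", "1" = "unaffected")[f[[6]]] %|NA|% "unknown",
      carrier = if (length(f) == 7L) {
        c("2" = "carrier", "1" = "non_carrier")[f[[7]]] %|NA|% "untested"
      } else "untested"
    )
  })
  ped <- dplyr::bind_rows(rows)
  validate_pedigree(ped, lines)
  ped
}

`%|NA|%` <- function(x, default) {
  x <- unname(x)
  if (is.na(x)) default else x
}

validate_pedigree <- function(ped, lines = NULL) {
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    if (anyDuplicated(sub$id)) {
      abort(paste0("duplicate individual id in family ", fam))
    }
    for (col in c("father_id", "mother_id")) {
      refs <- sub[[col]]
      missing <- refs[!is.na(refs) & !refs %in% sub$id]
      if (length(missing)) {
        ln <- NA_integer_
        if (!is.null(lines)) {
          fidx <- if (col == "father_id") 3L else 4L
          hit <- which(vapply(strsplit(trimws(lines), "\\s+"), function(f) {
            f[[1]] == fam && f[[fidx]] == missing[[1]]
          }, logical(1)))
          if (length(hit)) ln <- hit[[1]]
        }
        abort(paste0("family ", fam, ": parent id '", missing[[1]],
                     "' not found", if (!is.na(ln)) paste0(" (line ", ln, ")") else ""))
      }
    }
    # acyclicity: repeatedly peel individuals whose parents are all peeled
    remaining <- sub$id
    repeat {
      parents_of <- function(i) {
        r <- sub[sub$id == i, ]
        stats::na.omit(c(r$father_id, r$mother_id))
      }
      peel <- remaining[vapply(remaining, function(i) !any(parents_of(i) %in% remaining),
                               logical(1))]
      if (!length(peel)) break
      remaining <- setdiff(remaining, peel)
    }
    if (length(remaining)) {
      abort(paste0("family ", fam, ": pedigree contains a cycle involving ",
                   paste(remaining, collapse = ", ")))
    }
  }
  invisible(ped)
}

#' Count informative meioses for co-segregation
#'
#' In `affected_only` mode, m = (number of affected carriers) - 1: the index
#' carrier anchors the disease haplotype and is not itself an observed
#' meiosis. In `full` mode, each unaffected non-carrier offspring of a
#' carrier additionally counts as one informative meiosis (the variant was
#' observed *not* to travel with the unaffected phenotype). Untested
#' individuals contribute nothing in either mode.
#'
#' @param ped A pedigree tibble from [read_ped()], restricted to one family
#'   (or pass `family` to select one).
#' @param mode `"affected_only"` (default) or `"full"`.
#' @param family Optional family id to filter on.
#' @return Integer count of informative meioses.
#' @export
count_informative_meioses <- function(ped, mode = c("affected_only", "full"),
                                      family = NULL) {
  mode <- match.arg(mode)
  if (!is.null(family)) ped <- ped[ped$family_id == family, ]
  if (!nrow(ped)) abort("no individuals in pedigree")
  if (length(unique(ped$family_id)) > 1) {
    abort("pedigree contains multiple families; pass `family` to select one")
  }
  ac <- ped$affected == "affected" & ped$carrier == "carrier"
  n_ac <- sum(ac)
  if (n_ac == 0L) abort("no affected carriers in pedigree; eLOD undefined")
  m <- n_ac - 1L
  if (mode == "full") {
    carriers <- ped$id[ped$carrier == "carrier"]
    extra <- ped$affected == "unaffected" & ped$carrier == "non_carrier" &
      ((!is.na(ped$father_id) & ped$father_id %in% carriers) |
         (!is.na(ped$mother_id) & ped$mother_id %in% carriers))
    m <- m + sum(extra)
  }
  as.integer(m)
}

#' Co-segregation eLOD from informative meioses
#'
#' `elod(m) = m * log10(2)`. Display convention is two decimals
#' (round-half-even, R's default).
#'
#' @param m Non-negative integer vector of informative meioses.
#' @return Numeric eLOD values (unrounded).
#' @export
#' @examples
#' elod(4) # ~1.204, displayed 1.20
elod <- function(m) {
  if (any(is.na(m)) || any(m < 0)) abort("m must be a non-negative integer")
  m * log10(2)
}

#' Map an eLOD to a PP1 applied strength
#'
#' Thresholds: below 0.6 the co-segregation evidence is not applied; 0.6 up
#' to 1.2 supports at default (supporting) strength; 1.2 up to 1.5 at
#' moderate; 1.5 and above at strong.
#'
#' @param x Numeric vector of non-negative eLOD values.
#' @return Character vector in `{"none","supporting","moderate","strong"}`.
#' @export
#' @examples
#' pp1_strength(elod(0:7))
pp1_strength <- function(x) {
  if (any(is.na(x)) || any(x < 0)) abort("eLOD must be non-negative")
  dplyr::case_when(
    x >= 1.5 ~ "strong",
    x >= 1.2 ~ "moderate",
    x >= 0.6 ~ "supporting",
    TRUE ~ "none"
  )
}

#' Score co-segregation across families
#'
#' Data-frame-first pipeline: takes a (multi-family) pedigree tibble and
#' returns one row per family with the affected-carrier count, informative
#' meioses, eLOD (raw and displayed at two decimals) and the mapped PP1
#' applied strength.
#'
#' @inheritParams count_informative_meioses
#' @return A tibble with columns `family_id`, `n_affected_carriers`, `m`,
#'   `elod`, `elod_display`, `pp1_strength`.
#' @export
cosegregate <- function(ped, mode = c("affected_only", "full")) {
  mode <- match.arg(mode)
  ped |>
    dplyr::group_split(.data$family_id) |>
    purrr::map(function(fam) {
      m <- count_informative_meioses(fam, mode = mode)
      e <- elod(m)
      tibble::tibble(
        family_id = fam$family_id[[1]],
        n_affected_carriers = sum(fam$affected == "affected" & fam$carrier == "carrier"),
        m = m,
        elod = e,
        elod_display = round(e, 2),
        pp1_strength = pp1_strength(e)
      )
    }) |>
    dplyr::bind_rows()
}
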