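# HGVS parsing and molecular-consequence classification.
#
# Scope is deliberately small: coding-DNA (c.) substitutions, deletions,
# duplications, insertions and delins, plus the protein-level (p.)
# descriptions needed to classify consequence. No transcript projection,
# no genome liftover, no validation against a reference sequence.

AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val", "Ter")
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
            "I", "L", "K", "M", "F", "P", "S", "T", "W",
            "Y", "V", "*")

#' Normalize an amino-acid code to the three-letter alphabet
#'
#' One-letter codes (including `*` for a stop) are accepted on input and
#' converted; three-letter codes are case-normalized. Anything else is an
#' error.
#'
#' @param x Character vector of amino-acid codes.
#' @return Character vector of three-letter codes (`"Ter"` for stop).
#' @export
#' @examples
#' aa3("C")
#' aa3("cys")
aa3 <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    xi <- x[[i]]
    if (is.na(xi)) {
      out[[i]] <- NA_character_
      next
    }
    if (nchar(xi) == 1L) {
      hit <- match(toupper(xi), AA_ONE)
      if (is.na(hit)) abort(paste0("unknown one-letter amino-acid code: '", xi, "'"))
      out[[i]] <- AA_THREE[[hit]]
    } else {
      norm <- paste0(toupper(substr(xi, 1, 1)), tolower(substr(xi, 2, nchar(xi))))
      if (!norm %in% AA_THREE) abort(paste0("unknown amino-acid code: '", xi, "'"))
      out[[i]] <- norm
    }
  }
  out
}

CONSEQUENCE_LEVELS <- c("missense", "synonymous", "frameshift", "splice_site",
                        "nonsense", "inframe_indel", "unknown")

# --- single-description parsers ---------------------------------------------

# Parse the c. part. Returns a list of components or aborts on a malformed
# token. Published tables sometimes typeset "c.6615A > G" with spaces, so all
# internal whitespace is stripped first.
parse_cdna <- function(hgvs_c) {
  raw <- hgvs_c
  x <- gsub("\\s+", "", hgvs_c)
  if (!startsWith(x, "c.")) {
    abort(paste0("malformed HGVS cDNA description (must begin 'c.'): '", raw, "'"))
  }
  body <- substr(x, 3, nchar(x))

  sub_re <- "^(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$"
  range_re <- "^(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?"
  if (grepl(sub_re, body)) {
    m <- regmatches(body, regexec(sub_re, body))[[1]]
    offset <- if (m[[3]] == "") 0L else as.integer(m[[3]])
    ref <- m[[4]]
    alt <- m[[5]]
    if (ref == alt) {
      abort(paste0("malformed HGVS: reference and alternate base are identical in '", raw, "'"))
    }
    norm <- paste0("c.", m[[2]], if (offset != 0L) sprintf("%+d", offset) else "",
                   ref, ">", alt)
    return(list(kind = "substitution", start = as.integer(m[[2]]), end = as.integer(m[[2]]),
                offset = offset, ref = ref, alt = alt, normalized = norm))
  }

  indel_re <- paste0(range_re, "(delins|del|dup|ins)([ACGT]*)$")
  if (grepl(indel_re, body)) {
    m <- regmatches(body, regexec(indel_re, body))[[1]]
    start <- as.integer(m[[2]])
    end <- if (m[[4]] == "") start else as.integer(m[[4]])
    off1 <- if (m[[3]] == "") 0L else as.integer(m[[3]])
    off2 <- if (m[[5]] == "") 0L else as.integer(m[[5]])
    op <- m[[6]]
    seq <- m[[7]]
    if (op == "ins" && seq == "") {
      abort(paste0("malformed HGVS: insertion without inserted sequence in '", raw, "'"))
    }
    # net length change, used for the in-frame test
    span <- end - start + 1L
    delta <- switch(op,
      del = -span,
      dup = span,
      ins = nchar(seq),
      delins = nchar(seq) - span
    )
    return(list(kind = op, start = start, end = end, offset = max(abs(off1), abs(off2)),
                ref = NA_character_, alt = NA_character_, delta = delta,
                normalized = paste0("c.", body)))
  }

  abort(paste0("malformed HGVS cDNA description: '", raw, "'"))
}

# Parse the p. part (may be absent). Parenthesized predictions p.(...) are
# the norm for variants not confirmed at the protein level.
parse_protein <- function(hgvs_p) {
  if (is.na(hgvs_p) || hgvs_p == "") {
    return(list(kind = "absent", ref = NA_character_, alt = NA_character_,
                pos = NA_integer_, fs_stop = NA_integer_, normalized = NA_character_))
  }
  raw <- hgvs_p
  x <- gsub("\\s+", "", hgvs_p)
  if (!startsWith(x, "p.")) {
    abort(paste0("malformed HGVS protein description (must begin 'p.'): '", raw, "'"))
  }
  body <- sub("^p\\.", "", x)
  paren <- grepl("^\\(.*\\)$", body)
  if (paren) body <- sub("^\\((.*)\\)$", "\\1", body)

  if (body == "?") {
    return(list(kind = "unknown_effect", ref = NA_character_, alt = NA_character_,
                pos = NA_integer_, fs_stop = NA_integer_, normalized = "p.(?)"))
  }

  aa_re <- "([A-Za-z]{3}|[A-Za-z*])"
  syn_re <- paste0("^", aa_re, "(\\d+)=$")
  fs_re <- paste0("^", aa_re, "(\\d+)", aa_re, "?fs(\\*(\\d+))?$")
  sub_re <- paste0("^", aa_re, "(\\d+)", aa_re, "$")

  wrap <- function(s) if (paren) paste0("p.(", s, ")") else paste0("p.", s)

  if (grepl(syn_re, body)) {
    m <- regmatches(body, regexec(syn_re, body))[[1]]
    ref <- aa3(m[[2]])
    return(list(kind = "synonymous", ref = ref, alt = ref, pos = as.integer(m[[3]]),
                fs_stop = NA_integer_, normalized = wrap(paste0(ref, m[[3]], "="))))
  }
  if (grepl(fs_re, body)) {
    m <- regmatches(body, regexec(fs_re, body))[[1]]
    ref <- aa3(m[[2]])
    alt <- if (m[[4]] == "") NA_character_ else aa3(m[[4]])
    fs_stop <- if (m[[6]] == "") NA_integer_ else as.integer(m[[6]])
    norm <- paste0(ref, m[[3]], if (!is.na(alt)) alt else "", "fs",
                   if (!is.na(fs_stop)) paste0("*", fs_stop) else "")
    return(list(kind = "frameshift", ref = ref, alt = alt, pos = as.integer(m[[3]]),
                fs_stop = fs_stop, normalized = wrap(norm)))
  }
  if (grepl(sub_re, body)) {
    m <- regmatches(body, regexec(sub_re, body))[[1]]
    ref <- aa3(m[[2]])
    alt <- aa3(m[[4]])
    if (ref == alt) {
      abort(paste0("malformed HGVS: identical reference and alternate residue in '",
                   raw, "' (use '=' for a synonymous change)"))
    }
    return(list(kind = "substitution", ref = ref, alt = alt, pos = as.integer(m[[3]]),
                fs_stop = NA_integer_, normalized = wrap(paste0(ref, m[[3]], alt))))
  }
  abort(paste0("malformed HGVS protein description: '", raw, "'"))
}

# Consequence precedence (total: every input gets exactly one class):
#   1. intron offset at +/-1 or +/-2    -> splice_site
#   2. frameshift protein term          -> frameshift
#   3. in-frame del/dup/ins/delins      -> inframe_indel
#   4. p.X#=                            -> synonymous
#   5. p.X#Y, Y != Ter                  -> missense
#   6. p.X#Ter                          -> nonsense
#   7. anything else                    -> unknown
classify_consequence <- function(cd, pr) {
  if (cd$offset != 0L && abs(cd$offset) <= 2L) return("splice_site")
  if (pr$kind == "frameshift") return("frameshift")
  if (cd$kind %in% c("del", "dup", "ins", "delins")) {
    if (cd$delta %% 3L == 0L) return("inframe_indel")
    return("unknown")
  }
  if (pr$kind == "synonymous") return("synonymous")
  if (pr$kind == "substitution") {
    if (pr$alt == "Ter") return("nonsense")
    return("missense")
  }
  "unknown"
}

#' Parse HGVS variant descriptions into an annotated variant table
#'
#' Takes coding-DNA (and optionally protein) HGVS strings and returns one row
#' per variant with the molecular consequence assigned by a fixed precedence:
#' canonical splice site (intron offset at positions +/-1 or +/-2), then
#' frameshift, in-frame indel, synonymous, missense and nonsense. Internal
#' whitespace (as in typeset tables, e.g. `"c.6615A > G"`) is stripped before
#' parsing, and one-letter amino-acid codes are normalized to three-letter
#' codes.
#'
#' @param hgvs_c Character vector of cDNA descriptions beginning `"c."`.
#' @param hgvs_p Optional character vector of protein descriptions beginning
#'   `"p."`; `NA` where absent.
#' @param gene_symbol,transcript_id Annotation carried through to the output;
#'   defaults are the fibrillin-1 gene this package ships a domain table for.
#' @param exon Optional integer vector of exon numbers.
#' @return A tibble with columns `gene_symbol`, `transcript_id`, `hgvs_c`,
#'   `hgvs_p` (normalized forms), `exon`, `consequence`, `domain_label`
#'   (`NA` until [annotate_domains()] is applied), `ref_residue`,
#'   `alt_residue`, `protein_position` and `fs_stop_offset`.
#' @export
#' @examples
#' parse_hgvs("c.364C > T", "p.(Arg122Cys)")
#' parse_hgvs("c.4210+1G > A")
parse_hgvs <- function(hgvs_c, hgvs_p = NA_character_,
                       gene_symbol = "FBN1", transcript_id = "NM_000138.5",
                       exon = NA_integer_) {
  n <- length(hgvs_c)
  hgvs_p <- rep_len(as.character(hgvs_p), n)
  exon <- rep_len(as.integer(exon), n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cd <- parse_cdna(hgvs_c[[i]])
    pr <- parse_protein(hgvs_p[[i]])
    cons <- classify_consequence(cd, pr)
    is_sub <- cons %in% c("missense", "nonsense", "synonymous")
    rows[[i]] <- tibble::tibble(
      gene_symbol = gene_symbol,
      transcript_id = transcript_id,
      hgvs_c = cd$normalized,
      hgvs_p = pr$normalized,
      exon = exon[[i]],
      consequence = cons,
      domain_label = NA_character_,
      ref_residue = if (is_sub || pr$kind == "frameshift") pr$ref else NA_character_,
      alt_residue = if (is_sub) pr$alt else NA_character_,
      protein_position = if (is_sub || pr$kind == "frameshift") pr$pos else NA_integer_,
      fs_stop_offset = pr$fs_stop
    )
  }
  dplyr::bind_rows(rows)
}

#' Parse a variant list data frame
#'
#' Data-frame-first wrapper around [parse_hgvs()]: takes a table with `hgvs_c`
#' and optional `hgvs_p` / `exon` / `family_id` columns (the layout of a
#' variant list TSV) and returns the annotated variant tibble with the input
#' identifier columns preserved.
#'
#' @param data A data frame with at least an `hgvs_c` column.
#' @inheritParams parse_hgvs
#' @return A tibble; see [parse_hgvs()].
#' @export
parse_variants <- function(data, gene_symbol = "FBN1", transcript_id = "NM_000138.5") {
  stopifnot(is.data.frame(data), "hgvs_c" %in% names(data))
  hp <- if ("hgvs_p" %in% names(data)) data$hgvs_p else NA_character_
  ex <- if ("exon" %in% names(data)) data$exon else NA_integer_
  out <- parse_hgvs(data$hgvs_c, hp, gene_symbol = gene_symbol,
                    transcript_id = transcript_id, exon = ex)
  id_cols <- intersect(c("family_id", "variant_key"), names(data))
  if (length(id_cols)) out <- dplyr::bind_cols(data[id_cols], out)
  out
}

#' Format parsed variants back to HGVS strings
#'
#' Inverse of [parse_hgvs()] for display: returns the normalized
#' (whitespace-free, three-letter residue) cDNA and protein descriptions.
#'
#' @param variants A tibble from [parse_hgvs()].
#' @return A tibble with columns `hgvs_c` and `hgvs_p`.
#' @export
format_hgvs <- function(variants) {
  tibble::tibble(hgvs_c = variants$hgvs_c, hgvs_p = variants$hgvs_p)
}
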