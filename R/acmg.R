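# ACMG/AMP evidence combination and Bayesian posterior probability of
# pathogenicity.
#
# Evidence codes may be applied at a strength other than their default
# ("PS4_Moderate" is PS4 counted as one moderate item). The categorical
# five-tier classification follows the 2015 combining rules, evaluated on
# applied strengths. Alongside it, the engine reports the posterior
# probability of pathogenicity under the exponential odds framework: a
# very-strong item carries odds O = 350, and strong/moderate/supporting
# items carry O^(1/2), O^(1/4), O^(1/8); benign items contribute reciprocal
# odds. With prior P, posterior = O_comb * P / ((O_comb - 1) * P + 1).

ACMG_CODES <- tibble::tibble(
  code = c("PVS1",
           paste0("PS", 1:4),
           paste0("PM", 1:6),
           paste0("PP", 1:5),
           "BA1",
           paste0("BS", 1:4),
           paste0("BP", 1:7)),
  polarity = c(rep("pathogenic", 1 + 4 + 6 + 5), rep("benign", 1 + 4 + 7)),
  default_strength = c("very_strong",
                       rep("strong", 4),
                       rep("moderate", 6),
                       rep("supporting", 5),
                       "standalone",
                       rep("strong", 4),
                       rep("supporting", 7))
)

STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong", "standalone")

# log-odds exponents relative to a very-strong item
STRENGTH_EXPONENT <- c(very_strong = 1, standalone = 1, strong = 1 / 2,
                       moderate = 1 / 4, supporting = 1 / 8)

#' Parse ACMG/AMP evidence tokens
#'
#' Tokens are either a bare code (`"PM2"`, default strength) or a
#' strength-modified code (`"PS4_Moderate"`, `"PP1_Strong"`). A
#' semicolon-separated string is also accepted.
#'
#' @param tokens Character vector of evidence tokens, or a single
#'   semicolon-separated string.
#' @param variant_key Optional identifier carried into the output.
#' @return A tibble (evidence set) with columns `variant_key`, `code`,
#'   `polarity`, `default_strength`, `applied_strength`. Duplicate codes are
#'   an error.
#' @export
#' @examples
#' parse_evidence("PM1; PM2; PS4_Moderate; PP2")
parse_evidence <- function(tokens, variant_key = NA_character_) {
  if (length(tokens) == 1L && grepl(";", tokens)) {
    tokens <- strsplit(tokens, ";")[[1]]
  }
  tokens <- trimws(tokens)
  tokens <- tokens[tokens != ""]
  if (!length(tokens)) {
    return(tibble::tibble(variant_key = character(), code = character(),
                          polarity = character(), default_strength = character(),
                          applied_strength = character()))
  }
  parts <- strsplit(tokens, "_", fixed = TRUE)
  code <- vapply(parts, `[[`, character(1), 1)
  suffix <- vapply(parts, function(p) if (length(p) > 1) paste(p[-1], collapse = "_") else NA_character_,
                   character(1))
  bad <- setdiff(code, ACMG_CODES$code)
  if (length(bad)) {
    abort(paste0("unknown ACMG evidence code(s): ",
                 paste(tokens[code %in% bad], collapse = ", ")))
  }
  strength_map <- c(verystrong = "very_strong", very_strong = "very_strong",
                    strong = "strong", moderate = "moderate",
                    supporting = "supporting", standalone = "standalone")
  applied <- character(length(tokens))
  for (i in seq_along(tokens)) {
    def <- ACMG_CODES$default_strength[match(code[[i]], ACMG_CODES$code)]
    if (is.na(suffix[[i]])) {
      applied[[i]] <- def
    } else {
      key <- tolower(suffix[[i]])
      if (!key %in% names(strength_map)) {
        abort(paste0("unknown strength suffix in token '", tokens[[i]], "'"))
      }
      applied[[i]] <- strength_map[[key]]
    }
  }
  if (anyDuplicated(code)) {
    abort(paste0("duplicate evidence code(s) in set: ",
                 paste(unique(code[duplicated(code)]), collapse = ", ")))
  }
  tibble::tibble(
    variant_key = variant_key,
    code = code,
    polarity = ACMG_CODES$polarity[match(code, ACMG_CODES$code)],
    default_strength = ACMG_CODES$default_strength[match(code, ACMG_CODES$code)],
    applied_strength = applied
  )
}

# counts of items per polarity x applied strength
strength_counts <- function(ev) {
  cnt <- function(pol, s) sum(ev$polarity == pol & ev$applied_strength == s)
  list(
    p_vs = cnt("pathogenic", "very_strong"),
    p_s = cnt("pathogenic", "strong"),
    p_m = cnt("pathogenic", "moderate"),
    p_p = cnt("pathogenic", "supporting"),
    b_sa = cnt("benign", "standalone"),
    b_s = cnt("benign", "strong"),
    b_p = cnt("benign", "supporting") + cnt("benign", "moderate")
  )
}

#' Combine an evidence set into a five-tier classification
#'
#' Applies the 2015 categorical combining rules to the *applied* strengths.
#' Pathogenic: very-strong plus (one strong, two moderate, one moderate plus
#' one supporting, or two supporting); two strong; or one strong plus (three
#' moderate, two moderate plus two supporting, or one moderate plus four
#' supporting). Likely pathogenic: very-strong plus one moderate; one strong
#' plus one or two moderate; one strong plus two supporting; three moderate;
#' two moderate plus two supporting; or one moderate plus four supporting.
#' Benign: BA1, or two benign-strong. Likely benign: one benign-strong plus
#' one benign-supporting, or two benign-supporting. If rules of both
#' polarities fire, or none fires, the result is uncertain significance.
#'
#' @param ev An evidence set from [parse_evidence()].
#' @return A list with `classification`, `fired_rule` and the per-polarity
#'   strength counts.
#' @export
#' @examples
#' combine_acmg(parse_evidence("PVS1;PM2;PM6;PS4_Supporting"))
combine_acmg <- function(ev) {
  k <- strength_counts(ev)
  path_rule <- NULL
  if (k$p_vs >= 1 && (k$p_s >= 1 || k$p_m >= 2 || (k$p_m >= 1 && k$p_p >= 1) || k$p_p >= 2)) {
    path_rule <- "pathogenic: PVS + (S | 2M | M+P | 2P)"
  } else if (k$p_s >= 2) {
    path_rule <- "pathogenic: >=2S"
  } else if (k$p_s >= 1 && (k$p_m >= 3 || (k$p_m == 2 && k$p_p >= 2) || (k$p_m == 1 && k$p_p >= 4))) {
    path_rule <- "pathogenic: S + (>=3M | 2M+>=2P | M+>=4P)"
  }
  lp_rule <- NULL
  if (is.null(path_rule)) {
    if (k$p_vs >= 1 && k$p_m >= 1) {
      lp_rule <- "likely_pathogenic: PVS + M"
    } else if (k$p_s >= 1 && k$p_m >= 1 && k$p_m <= 2) {
      lp_rule <- "likely_pathogenic: S + 1-2M"
    } else if (k$p_s >= 1 && k$p_p >= 2) {
      lp_rule <- "likely_pathogenic: S + >=2P"
    } else if (k$p_m >= 3) {
      lp_rule <- "likely_pathogenic: >=3M"
    } else if (k$p_m == 2 && k$p_p >= 2) {
      lp_rule <- "likely_pathogenic: 2M + >=2P"
    } else if (k$p_m == 1 && k$p_p >= 4) {
      lp_rule <- "likely_pathogenic: M + >=4P"
    }
  }
  ben_rule <- NULL
  if (k$b_sa >= 1) {
    ben_rule <- "benign: BA1"
  } else if (k$b_s >= 2) {
    ben_rule <- "benign: >=2 BS"
  }
  lb_rule <- NULL
  if (is.null(ben_rule)) {
    if (k$b_s == 1 && k$b_p >= 1) {
      lb_rule <- "likely_benign: BS + BP"
    } else if (k$b_p >= 2) {
      lb_rule <- "likely_benign: >=2 BP"
    }
  }

  path_side <- path_rule %||% lp_rule
  ben_side <- ben_rule %||% lb_rule
  if (!is.null(path_side) && !is.null(ben_side)) {
    cls <- "uncertain_significance"
    rule <- paste0("conflicting: [", path_side, "] vs [", ben_side, "]")
  } else if (!is.null(path_rule)) {
    cls <- "pathogenic"; rule <- path_rule
  } else if (!is.null(lp_rule)) {
    cls <- "likely_pathogenic"; rule <- lp_rule
  } else if (!is.null(ben_rule)) {
    cls <- "benign"; rule <- ben_rule
  } else if (!is.null(lb_rule)) {
    cls <- "likely_benign"; rule <- lb_rule
  } else {
    cls <- "uncertain_significance"; rule <- "none"
  }
  list(classification = cls, fired_rule = rule, strength_counts = k)
}

#' Bayesian posterior probability of pathogenicity
#'
#' Each pathogenic item contributes a positive exponent on the very-strong
#' odds (1 for very strong, 1/2 strong, 1/4 moderate, 1/8 supporting); each
#' benign item the negative of the same exponent (BA1 counted like a
#' very-strong item). Combined odds `O = odds_very_strong^sum(exponents)`;
#' posterior `= O * prior / ((O - 1) * prior + 1)`. With no evidence the
#' posterior equals the prior.
#'
#' @param ev An evidence set from [parse_evidence()].
#' @param prior Prior probability of pathogenicity (default 0.10).
#' @param odds_very_strong Odds of a very-strong pathogenic item (default 350).
#' @return Posterior probability in (0, 1).
#' @export
#' @examples
#' bayes_posterior(parse_evidence("PM2;PP3;PP4")) # one moderate + two supporting
bayes_posterior <- function(ev, prior = 0.10, odds_very_strong = 350) {
  stopifnot(prior > 0, prior < 1, odds_very_strong > 1)
  if (!nrow(ev)) return(prior)
  expo <- STRENGTH_EXPONENT[ev$applied_strength]
  signed <- ifelse(ev$polarity == "pathogenic", expo, -expo)
  odds <- odds_very_strong^sum(signed)
  odds * prior / ((odds - 1) * prior + 1)
}

#' Classify a cohort of evidence sets
#'
#' Data-frame-first driver: takes a table with `variant_key` and `evidence`
#' (semicolon-separated tokens) — the layout of an evidence TSV — and runs
#' the combining rules and the Bayesian posterior on every variant.
#'
#' @param data A data frame with columns `variant_key` and `evidence`.
#' @param prior,odds_very_strong Passed to [bayes_posterior()].
#' @return An object of class `acmg_cohort`: a tibble with one row per
#'   variant (`variant_key`, `classification`, `fired_rule`, `posterior`,
#'   `posterior_percent` at one decimal, `n_items`) plus the parsed evidence
#'   in the `evidence` attribute. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
classify_variants <- function(data, prior = 0.10, odds_very_strong = 350) {
  stopifnot(is.data.frame(data), all(c("variant_key", "evidence") %in% names(data)),
            nrow(data) > 0)
  sets <- purrr::map2(data$evidence, data$variant_key, parse_evidence)
  rows <- purrr::map2(sets, data$variant_key, function(ev, key) {
    comb <- combine_acmg(ev)
    post <- bayes_posterior(ev, prior = prior, odds_very_strong = odds_very_strong)
    tibble::tibble(
      variant_key = key,
      classification = comb$classification,
      fired_rule = comb$fired_rule,
      posterior = post,
      posterior_percent = round(100 * post, 1),
      n_items = nrow(ev)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "evidence") <- sets
  attr(out, "params") <- list(prior = prior, odds_very_strong = odds_very_strong)
  class(out) <- c("acmg_cohort", class(out))
  out
}

#' @method tidy acmg_cohort
#' @export
tidy.acmg_cohort <- function(x, ...) {
  out <- x
  attr(out, "evidence") <- NULL
  attr(out, "params") <- NULL
  class(out) <- setdiff(class(out), "acmg_cohort")
  out
}

#' @method glance acmg_cohort
#' @export
glance.acmg_cohort <- function(x, ...) {
  cls <- factor(x$classification,
                levels = c("pathogenic", "likely_pathogenic", "uncertain_significance",
                           "likely_benign", "benign"))
  counts <- table(cls)
  tibble::tibble(
    n_variants = nrow(x),
    n_pathogenic = unname(counts[["pathogenic"]]),
    n_likely_pathogenic = unname(counts[["likely_pathogenic"]]),
    n_uncertain = unname(counts[["uncertain_significance"]]),
    n_likely_benign = unname(counts[["likely_benign"]]),
    n_benign = unname(counts[["benign"]]),
    n_lp_plus_p = unname(counts[["pathogenic"]] + counts[["likely_pathogenic"]])
  )
}

#' @method print acmg_cohort
#' @export
print.acmg_cohort <- function(x, ...) {
  g <- glance(x)
  cat("ACMG classification of", g$n_variants, "variant(s):",
      g$n_lp_plus_p, "likely pathogenic/pathogenic\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @method autoplot acmg_cohort
#' @export
autoplot.acmg_cohort <- function(object, ...) {
  df <- tidy(object)
  df$variant_key <- factor(df$variant_key, levels = df$variant_key[order(df$posterior)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior_percent, y = .data$variant_key,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 100 * attr(object, "params")$prior,
                        linetype = "dashed") +
    ggplot2::labs(x = "posterior probability of pathogenicity (%)", y = NULL,
                  fill = "classification") +
    ggplot2::theme_minimal()
}
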