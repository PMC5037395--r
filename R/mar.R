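# Rule-based sliding-window MAR (matrix attachment region) potential.

#' Sliding-window configuration for MAR scoring
#'
#' Defaults are the classic MAR-Wiz settings: window width 1000 bp, slide
#' 100 bp, cutoff 0.60, run length 3.
#'
#' @param window_width Window width in bp.
#' @param slide Slide distance in bp (`window_width >= slide >= 1`).
#' @param cutoff Potential threshold in `[0, 1]` for region calling.
#' @param run_length Minimum number of consecutive qualifying windows.
#' @return A `mar_config` list.
#' @export
mar_config <- function(window_width = 1000, slide = 100, cutoff = 0.60,
                       run_length = 3) {
  window_width <- as.integer(window_width); slide <- as.integer(slide)
  run_length <- as.integer(run_length)
  if (slide < 1L || window_width < slide) {
    stop("need window_width >= slide >= 1", call. = FALSE)
  }
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]",
                                     call. = FALSE)
  if (run_length < 1L) stop("run_length must be >= 1", call. = FALSE)
  structure(list(window_width = window_width, slide = slide,
                 cutoff = cutoff, run_length = run_length),
            class = "mar_config")
}

#' Define a MAR scoring rule
#'
#' Two rule types exist.  Pattern rules score
#' `min(1, hits / saturation_count)` where hits are counted for every listed
#' pattern on both strands with overlaps allowed; patterns are IUPAC strings
#' and may contain fixed gaps written `X{n}` (n unconstrained bases).  The
#' composition rule (`type = "at_content"`) scores
#' `clamp((AT_fraction - 0.5) / 0.25, 0, 1)`, reaching 1 at 75% A+T.
#'
#' @param name Rule name.
#' @param patterns Character vector of IUPAC patterns (pattern rules).
#' @param weight Positive weight in the combined potential.
#' @param saturation_count Hit count at which the score saturates at 1.
#' @param type `"pattern"` or `"at_content"`.
#' @return A `mar_rule` list.
#' @export
mar_rule <- function(name, patterns = character(0), weight = 1,
                     saturation_count = 1, type = c("pattern", "at_content")) {
  type <- match.arg(type)
  if (weight <= 0) stop("weight must be positive", call. = FALSE)
  saturation_count <- as.integer(saturation_count)
  if (saturation_count < 1L) stop("saturation_count must be >= 1",
                                  call. = FALSE)
  if (type == "pattern" && !length(patterns)) {
    stop("pattern rule needs at least one pattern", call. = FALSE)
  }
  structure(list(name = name, patterns = toupper(patterns), weight = weight,
                 saturation_count = saturation_count, type = type),
            class = "mar_rule")
}

# Expand fixed-gap syntax X{n} to n unconstrained IUPAC N positions.
expand_gaps <- function(pattern) {
  while (grepl("X\\{\\d+\\}", pattern)) {
    m <- regmatches(pattern, regexpr("X\\{\\d+\\}", pattern))
    n <- as.integer(sub("X\\{(\\d+)\\}", "\\1", m))
    pattern <- sub("X\\{\\d+\\}", strrep("N", n), pattern)
  }
  pattern
}

#' Default MAR rule set
#'
#' Six canonical rule families used by rule-based MAR finders: AT-rich
#' origin-of-replication signals, TG-richness, curved DNA, kinked DNA, the
#' vertebrate topoisomerase II consensus, and window AT-richness.  The
#' pattern strings follow the rule families of the original MAR-finder
#' literature; every pattern, weight and saturation count is overridable via
#' [mar_rule()] or a YAML rules file ([read_mar_rules()]), so the scoring
#' engine is independent of any one pattern set.
#'
#' @return A list of `mar_rule` objects.
#' @export
default_mar_rules <- function() {
  list(
    mar_rule("ori_signal", c("ATTA", "ATTTA", "ATTTTA"),
             weight = 1, saturation_count = 12),
    mar_rule("tg_richness", c("TGTTTTG", "TGTTTTTTG"),
             weight = 1, saturation_count = 2),
    mar_rule("curved_dna",
             c("AAAAX{6}AAAAX{6}AAAA", "TTTTX{6}TTTTX{6}TTTT", "TTTAAA"),
             weight = 1, saturation_count = 2),
    mar_rule("kinked_dna",
             c("TAX{3}TGX{3}CA", "TAX{3}CAX{3}TG", "TGX{3}TAX{3}CA",
               "TGX{3}CAX{3}TA", "CAX{3}TAX{3}TG", "CAX{3}TGX{3}TA"),
             weight = 1, saturation_count = 4),
    mar_rule("topo_ii", c("RNYNNCNNGYNGKTNYNY", "GTNWAYATTNATNNR"),
             weight = 1, saturation_count = 2),
    mar_rule("at_richness", weight = 1, type = "at_content")
  )
}

#' Read / write MAR rules as YAML
#'
#' The rules file is a YAML list with fields `name`, `type` (optional,
#' default `"pattern"`), `patterns`, `weight`, `saturation_count`.
#'
#' @param path YAML file path.
#' @return `read_mar_rules`: list of `mar_rule`; `write_mar_rules`: `path`.
#' @export
read_mar_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    mar_rule(name = r$name,
             patterns = as.character(r$patterns %||% character(0)),
             weight = r$weight %||% 1,
             saturation_count = r$saturation_count %||% 1,
             type = r$type %||% "pattern")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_mar_rules
#' @param rules List of `mar_rule` objects.
#' @export
write_mar_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, unclass), path)
  invisible(path)
}

#' Sliding windows over a sequence length
#'
#' Windows are `[k * slide, k * slide + window_width)` for
#' `k = 0 .. floor((L - W) / S)`; a trailing remainder shorter than the
#' window width is discarded.
#'
#' @param seq_length Sequence length in bp (>= window width).
#' @param config A [mar_config()].
#' @return Data frame of `start`, `end` (0-based half-open).
#' @export
sliding_windows <- function(seq_length, config = mar_config()) {
  seq_length <- as.integer(seq_length)
  if (seq_length < config$window_width) {
    stop("sequence shorter than window width", call. = FALSE)
  }
  k <- 0:((seq_length - config$window_width) %/% config$slide)
  data.frame(start = k * config$slide,
             end = k * config$slide + config$window_width)
}

#' Score one window under one MAR rule
#'
#' @param window_seq Window sequence (uppercase DNA).
#' @param rule A [mar_rule()].
#' @return Score in `[0, 1]`.
#' @export
rule_score <- function(window_seq, rule) {
  stopifnot(inherits(rule, "mar_rule"))
  if (rule$type == "at_content") {
    n <- nchar(window_seq)
    if (n == 0L) return(0)
    at <- nchar(gsub("[^AT]", "", window_seq))
    return(max(0, min(1, (at / n - 0.5) / 0.25)))
  }
  hits <- 0L
  for (p in rule$patterns) {
    p <- expand_gaps(p)
    hits <- hits + length(regex_starts0(window_seq, iupac_regex(p))) +
      length(regex_starts0(window_seq,
                           iupac_regex(reverse_complement(p))))
  }
  min(1, hits / rule$saturation_count)
}

#' MAR-potential profile of a sequence
#'
#' Scores every sliding window under every rule and combines the rule scores
#' into a per-window potential in `[0, 1]` by the weighted mean
#' `sum(w_r * s_r) / sum(w_r)`.  Deterministic: identical sequence, rules
#' and configuration give a bit-identical profile.
#'
#' @param seq Uppercase DNA string (length >= window width).
#' @param rules Non-empty list of [mar_rule()] (default
#'   [default_mar_rules()]).
#' @param config A [mar_config()].
#' @return A `mar_profile` list: `window_starts`, `window_width`,
#'   `rule_scores` (windows x rules matrix), `potential`, `config`,
#'   `combiner = "weighted_mean"`.
#' @export
mar_profile <- function(seq, rules = default_mar_rules(),
                        config = mar_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!length(rules)) stop("empty rule list", call. = FALSE)
  wins <- sliding_windows(nchar(seq), config)
  weights <- vapply(rules, `[[`, numeric(1), "weight")
  scores <- matrix(0, nrow = nrow(wins), ncol = length(rules),
                   dimnames = list(NULL,
                                   vapply(rules, `[[`, character(1), "name")))
  for (w in seq_len(nrow(wins))) {
    ws <- substr(seq, wins$start[w] + 1L, wins$end[w])
    for (r in seq_along(rules)) scores[w, r] <- rule_score(ws, rules[[r]])
  }
  structure(list(
    window_starts = wins$start,
    window_width = config$window_width,
    rule_scores = scores,
    potential = as.numeric(scores %*% weights) / sum(weights),
    config = config,
    combiner = "weighted_mean"
  ), class = "mar_profile")
}

# Internal constructor used by tests and region calling on synthetic
# potential vectors.
mar_profile_from_potential <- function(potential, config = mar_config()) {
  structure(list(
    window_starts = seq_along(potential) * config$slide - config$slide,
    window_width = config$window_width,
    rule_scores = NULL,
    potential = as.numeric(potential),
    config = config,
    combiner = "weighted_mean"
  ), class = "mar_profile")
}

#' Call MAR regions from a potential profile
#'
#' Maximal runs of at least `run_length` consecutive windows with potential
#' `>= cutoff` become regions spanning from the first window's start to the
#' last window's end.
#'
#' @param profile A `mar_profile`.
#' @param config A [mar_config()] (defaults to the profile's own).
#' @return Data frame `start`, `end`, `n_windows`, `max_potential`.
#' @export
call_mar_regions <- function(profile, config = NULL) {
  stopifnot(inherits(profile, "mar_profile"))
  if (is.null(config)) config <- profile$config
  ok <- profile$potential >= config$cutoff
  r <- rle(ok)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values & r$lengths >= config$run_length
  out <- data.frame(
    start = profile$window_starts[starts_idx[keep]],
    end = profile$window_starts[ends_idx[keep]] + profile$window_width,
    n_windows = r$lengths[keep]
  )
  out$max_potential <- vapply(which(keep), function(j) {
    max(profile$potential[starts_idx[j]:ends_idx[j]])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Write a MAR profile as a plottable TSV
#'
#' Per-window table (`start`, `end`, one column per rule, `potential`) with
#' a `#` header line; combiner noted in the header comment.
#'
#' @param profile A `mar_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mar_profile <- function(profile, path) {
  stopifnot(inherits(profile, "mar_profile"))
  df <- data.frame(start = profile$window_starts,
                   end = profile$window_starts + profile$window_width)
  if (!is.null(profile$rule_scores)) df <- cbind(df, profile$rule_scores)
  df$potential <- profile$potential
  write_tsv_report(df, path)
}

#' Plot a MAR-potential profile
#'
#' Base-graphics line plot of potential against window start (bp), with the
#' calling cutoff drawn as a dashed line.
#'
#' @param x A `mar_profile`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mar_profile <- function(x, ...) {
  plot(x$window_starts, x$potential, type = "l", ylim = c(0, 1),
       xlab = "position (bp)", ylab = "MAR potential", ...)
  graphics::abline(h = x$config$cutoff, lty = 2)
  invisible(x)
}
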