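# Consensus deleteriousness screen over a multi-predictor score table.
#
# Nine tools are consumed as scores (none is re-implemented): SIFT,
# PolyPhen-2 (HumDiv and HumVar jointly, one tool), MAPP, PANTHER,
# SNP&GO, PhD-SNP, PredictSNP, PROVEAN and I-Mutant. A variant is
# consensus-deleterious when at least `min_tools` tools call it
# deleterious; a missing score is a no-call, never a neutral call.

#' Parse a protein substitution string
#'
#' Accepts the usual `G1050V` form: wild-type residue, position, mutant
#' residue, validated against the 20 one-letter amino-acid codes.
#'
#' @param text a single string such as `"G1050V"`.
#' @return list with `wild`, `position`, `mutant`.
#' @export
parse_substitution <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))[[1]]
  if (length(m) != 4)
    stop("parse error: substitution '", text, "' is not letter-digits-letter")
  wild <- toupper(m[2]); mutant <- toupper(m[4])
  pos <- as.integer(m[3])
  bad <- setdiff(c(wild, mutant), .aa_one)
  if (length(bad))
    stop("alphabet error: invalid residue letter(s) '",
         paste(bad, collapse = "', '"), "' in '", text, "'")
  if (pos < 1) stop("parse error: position must be >= 1 in '", text, "'")
  if (wild == mutant)
    stop("parse error: wild-type and mutant residues are identical in '",
         text, "'")
  list(wild = wild, position = pos, mutant = mutant)
}

#' Per-tool deleteriousness cutoffs
#'
#' The default rules: SIFT <= 0.05; PolyPhen-2 HumDiv > 0.9 AND
#' HumVar > 0.9 (jointly, one tool); PROVEAN <= -2.5; I-Mutant < -0.5;
#' PhD-SNP > 0.5; SNP&GO > 0.5; PANTHER >= 0.5; PredictSNP and MAPP:
#' categorical "D", or score > 0.5. Boundaries are applied exactly as
#' written (SIFT at 0.05 is deleterious, I-Mutant at -0.5 is not).
#'
#' @return named list of rules, one per tool; each has `columns`, `op`,
#'   `threshold` and `categorical`.
#' @export
default_cutoffs <- function() {
  rule <- function(columns, op, threshold, categorical = FALSE)
    list(columns = columns, op = op, threshold = threshold,
         categorical = categorical)
  list(
    SIFT       = rule("SIFT", "<=", 0.05),
    PolyPhen2  = rule(c("PolyPhen2_HumDiv", "PolyPhen2_HumVar"), ">", 0.9),
    MAPP       = rule("MAPP", ">", 0.5, categorical = TRUE),
    PANTHER    = rule("PANTHER", ">=", 0.5),
    SNP_GO     = rule("SNP_GO", ">", 0.5),
    PhD_SNP    = rule("PhD_SNP", ">", 0.5),
    PredictSNP = rule("PredictSNP", ">", 0.5, categorical = TRUE),
    PROVEAN    = rule("PROVEAN", "<=", -2.5),
    I_Mutant   = rule("I_Mutant", "<", -0.5))
}

#' Read a delimited variant score table
#'
#' Reads a CSV or TSV with a header row naming the predictors; `-` and
#' empty cells are missing scores; `D`/`N` are accepted for categorical
#' tools.
#'
#' @param path file path (`.tsv`/`.txt` read as tab-separated, otherwise
#'   comma-separated).
#' @return data.frame with `rs_id`, `substitution` and one column per
#'   score.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         na.strings = c("-", "", "NA"), check.names = TRUE)
  need <- c("rs_id", "substitution")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("score table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

# one tool's calls over all rows: "deleterious" / "neutral" / "no_call"
.tool_call <- function(tab, tool, rule) {
  miss <- setdiff(rule$columns, names(tab))
  if (length(miss))
    stop("score table lacks column(s) for tool ", tool, ": ",
         paste(miss, collapse = ", "))
  per_col <- lapply(rule$columns, function(cc) {
    v <- tab[[cc]]
    out <- rep(NA, length(v))              # logical: passes cutoff?
    chr <- as.character(v)
    present <- !is.na(v) & !(trimws(chr) %in% c("", "-"))
    if (rule$categorical) {
      lab <- toupper(trimws(chr))
      cat_rows <- present & lab %in% c("D", "N")
      out[cat_rows] <- lab[cat_rows] == "D"
      present <- present & !cat_rows
    }
    num <- suppressWarnings(as.numeric(chr))
    bad <- present & is.na(num)
    if (any(bad))
      stop("value error: non-numeric score '", chr[which(bad)[1]],
           "' in column ", cc, ", row ", which(bad)[1])
    cmp <- switch(rule$op,
                  "<=" = num <= rule$threshold,
                  "<"  = num <  rule$threshold,
                  ">=" = num >= rule$threshold,
                  ">"  = num >  rule$threshold)
    out[present] <- cmp[present]
    out
  })
  pass <- Reduce(function(a, b) a & b, per_col)   # all columns must pass
  ifelse(is.na(pass), "no_call", ifelse(pass, "deleterious", "neutral"))
}

#' Apply per-tool cutoffs to a score table
#'
#' @param tab a score table as from [read_score_table()] or
#'   [generate_score_table()].
#' @param cutoffs rule list, see [default_cutoffs()].
#' @return character matrix (variants x tools) of calls in
#'   `deleterious` / `neutral` / `no_call`.
#' @export
apply_cutoffs <- function(tab, cutoffs = default_cutoffs()) {
  calls <- vapply(names(cutoffs),
                  function(tool) .tool_call(tab, tool, cutoffs[[tool]]),
                  character(nrow(tab)))
  if (nrow(tab) == 1) calls <- matrix(calls, nrow = 1,
                                      dimnames = list(NULL, names(cutoffs)))
  rownames(calls) <- tab$rs_id
  calls
}

#' Consensus deleteriousness classification
#'
#' Counts, per variant, the tools calling it deleterious (no-calls never
#' count) and flags variants reaching `min_tools`. The result is sorted
#' by the deleterious-tool count (descending), then by rs id.
#'
#' @inheritParams apply_cutoffs
#' @param min_tools minimum number of deleterious calls for the
#'   consensus flag (default 7 of the 9 tools).
#' @return data.frame with `rs_id`, `substitution`, one call column per
#'   tool, `n_deleterious` and `is_consensus_deleterious`.
#' @export
consensus <- function(tab, cutoffs = default_cutoffs(), min_tools = 7) {
  if (nrow(tab) < 1) stop("need at least one variant record")
  calls <- apply_cutoffs(tab, cutoffs)
  n_del <- rowSums(calls == "deleterious")
  out <- data.frame(rs_id = tab$rs_id, substitution = tab$substitution,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
  out$n_deleterious <- as.integer(n_del)
  out$is_consensus_deleterious <- n_del >= min_tools
  out <- out[order(-out$n_deleterious, out$rs_id), ]
  rownames(out) <- NULL
  out
}

#' Pairwise tool-agreement (phi) matrix
#'
#' For each pair of tools, the phi coefficient (Pearson correlation of
#' the binary deleterious/neutral calls) over the variants where both
#' tools made a call. Pairs with no co-called variants, or where a tool's
#' calls have zero variance, are undefined and returned as `NA`.
#'
#' @inheritParams apply_cutoffs
#' @return symmetric 9 x 9 numeric matrix with unit diagonal.
#' @export
tool_agreement_matrix <- function(tab, cutoffs = default_cutoffs()) {
  if (nrow(tab) < 2) stop("need at least two variant records")
  calls <- apply_cutoffs(tab, cutoffs)
  bin <- matrix(NA_real_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  bin[calls == "deleterious"] <- 1
  bin[calls == "neutral"] <- 0
  k <- ncol(bin)
  phi <- matrix(NA_real_, k, k, dimnames = list(colnames(bin), colnames(bin)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) { phi[i, j] <- phi[j, i]; next }
    if (i == j) { phi[i, j] <- 1; next }
    both <- !is.na(bin[, i]) & !is.na(bin[, j])
    if (sum(both) < 2) next
    x <- bin[both, i]; y <- bin[both, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    phi[i, j] <- stats::cor(x, y)
  }
  phi
}
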