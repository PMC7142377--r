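# Shared test helpers: tiny assessment-table builders and derivation-cohort
# slices of the published reference counts.

# long-form assessment table from a list of (neonate, cohort, day, index,
# grades) entries; grades is a named character vector
make_assessments <- function(entries) {
  do.call(rbind, lapply(entries, function(e) {
    g <- e$grades
    if (length(g) == 0) return(NULL)
    data.frame(neonate_id = e$neonate, cohort_id = e$cohort,
               day_of_life = e$day, assessment_index = e$index,
               item_id = names(g), grade = unname(g),
               stringsAsFactors = FALSE)
  }))
}

# schedule covering every entry (so all-absent assessments exist)
make_schedule <- function(entries) {
  unique(do.call(rbind, lapply(entries, function(e) {
    data.frame(neonate_id = e$neonate, cohort_id = e$cohort,
               day_of_life = e$day, assessment_index = e$index,
               stringsAsFactors = FALSE)
  })))
}

# derivation-cohort endorsement counts/sizes from the packaged reference
deriv_counts <- function(id) {
  ref <- reference_endorsement_counts()
  as.integer(ref[ref$binary_id == id, c("louisville", "tufts", "kentucky")])
}
deriv_n <- function() {
  as.integer(attr(reference_endorsement_counts(), "cohort_n")[
    c("louisville", "tufts", "kentucky")])
}

# brute-force concordance by pair enumeration (independent oracle)
auc_bruteforce <- function(score, outcome) {
  pos <- score[as.logical(outcome)]
  neg <- score[!as.logical(outcome)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
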