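# Small in-code fixtures shared across test files.

# A 3-miRNA x 4-sample Ct matrix with one undetected well and a stable
# reference row.
tiny_ct <- function() {
  m <- rbind(
    "mir-a" = c(30, 31, 29, 30.5),
    "mir-b" = c(25, NA, 26, 25.5),
    "U6"    = c(25, 25, 25, 25)
  )
  colnames(m) <- c("S1", "S2", "S3", "S4")
  ct_matrix(m)
}

write_tmp_ct <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Exhaustive AUC oracle: concordant pairs + half ties over all
# case/control pairs.
brute_force_auc <- function(values, is_case) {
  cs <- values[is_case]; ks <- values[!is_case]
  tot <- 0
  for (a in cs) for (b in ks)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ks))
}

# Flow-event table builder: CD31+ then CD31- Annexin V+ gated events,
# then Annexin V- gated debris, then out-of-gate events.
make_events <- function(n_pos, n_neg, n_annneg = 0, n_out = 0) {
  data.frame(
    in_mp_gate = c(rep(TRUE, n_pos + n_neg + n_annneg), rep(FALSE, n_out)),
    annexinV = c(rep(TRUE, n_pos + n_neg), rep(FALSE, n_annneg),
                 rep(TRUE, n_out)),
    cd31 = c(rep(TRUE, n_pos), rep(FALSE, n_neg + n_annneg),
             rep(TRUE, n_out)))
}

# Exhaustive balanced-relabeling SAM null for small n: all index sets.
brute_force_null <- function(x, n1, s0) {
  sets <- utils::combn(ncol(x), n1, simplify = FALSE)
  t(vapply(sets, function(idx) {
    ic <- seq_len(ncol(x)) %in% idx
    unname(sort(circmir:::sam_dstat(x, ic, s0)$d, na.last = TRUE))
  }, numeric(nrow(x))))
}
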