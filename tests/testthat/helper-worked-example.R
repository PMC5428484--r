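# 15x5 semantic-similarity matrix realizing the published worked example:
# row-maxima sum 6.279957, column-maxima sum 2.837199, and one all-zero
# column (a fly-only term sharing no similarity with any query term).
worked_example_matrix <- function() {
  M <- matrix(0, 15, 5)
  col_max <- c(0.9, 0.6, 0.5, 0.837199, 0)   # sums to 2.837199
  M[1, 1:4] <- col_max[1:4]                  # row 1 peaks at 0.9
  row_rest <- c(rep(0.38, 13), 0.439957)     # rows 2..15; sums to 5.379957
  M[2:15, 1] <- row_rest
  stopifnot(all.equal(sum(apply(M, 1, max)), 6.279957),
            all.equal(sum(apply(M, 2, max)), 2.837199),
            all(M[, 5] == 0))
  M
}
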