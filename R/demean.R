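# Weighted within-transformation by alternating projections.
#
# Removes weighted group means of each column of M over every fixed-effect
# dimension in turn, sweeping until the largest single-sweep adjustment
# falls below `tol` relative to the scale of M (one dimension converges in
# a single pass; several dimensions converge geometrically, fast when the
# group structures are nested or nearly orthogonal). The sweep kernel is
# compiled (src/demean.cpp).
#
# fe_idx: list of integer vectors, each mapping rows to 1..K_d group codes.
.demean_fe <- function(M, w, fe_idx, tol = 1e-8, max_sweeps = 2000L) {
  M <- as.matrix(M)
  if (length(fe_idx) == 0) return(M)
  out <- cpp_demean(M, w, fe_idx, tol, as.integer(max_sweeps))
  if (!isTRUE(attr(out, "converged"))) {
    warn("Fixed-effect demeaning did not fully converge; results may be inexact.")
  }
  attr(out, "converged") <- NULL
  attr(out, "sweeps") <- NULL
  colnames(out) <- colnames(M)
  out
}

# Integer group codes for a fixed-effect key column.
.fe_codes <- function(x) {
  f <- factor(x)
  list(idx = as.integer(f), nlev = nlevels(f))
}
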