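# all 720 permutations of 1:6, for exhaustive permutation-test checks
gtools_permutations6 <- function() {
  perms <- matrix(1L, 1, 1)
  for (n in 2:6) {
    out <- matrix(0L, nrow(perms) * n, n)
    r <- 0L
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(n)) {
        r <- r + 1L
        out[r, ] <- append(perms[i, ], n, after = pos - 1L)
      }
    }
    perms <- out
  }
  perms
}
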