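# one-dimensional toy scale: every residue's single descriptor value is its
# alphabet index, except A = 1, G = 2 for the worked micro-examples
toy_scale_1d <- function() {
  v <- matrix(seq_along(pepqsar:::AA_ALPHABET), ncol = 1,
              dimnames = list(pepqsar:::AA_ALPHABET, "t1"))
  v["A", 1] <- 1; v["G", 1] <- 2
  as_scale(v, "toy1d")
}

random_peptide <- function(len) {
  paste(sample(pepqsar:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# naive positional-lookup encoder, independent of encode_peptide internals
naive_encode <- function(seq, k_n, k_c, fill, scale) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  d <- scale$dims
  out <- c()
  for (i in seq_len(k_n)) {
    out <- c(out, if (i <= len) scale$values[chars[i], ] else rep(fill, d))
  }
  for (j in seq_len(k_c)) {
    out <- c(out, if (j <= len) scale$values[chars[len - j + 1], ] else rep(fill, d))
  }
  unname(out)
}
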