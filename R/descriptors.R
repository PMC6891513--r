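AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Validate and canonicalize a peptide sequence
#'
#' Strips whitespace, upper-cases, and checks that every character is one of
#' the 20 standard one-letter amino-acid codes. Ambiguity and non-standard
#' codes (B, J, O, U, X, Z) are rejected.
#'
#' @param raw Character scalar, the raw sequence.
#' @return Canonical upper-case sequence string.
#' @export
#' @examples
#' validate_sequence("agyspigfvr")
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("sequence must be a single character string")
  }
  seq <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(seq)) stop("sequence is empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], seq))
  }
  seq
}

#' Load an amino-acid descriptor scale
#'
#' A descriptor scale maps each of the 20 standard residues to a short vector
#' of real-valued physicochemical property scores. Scales are read from a
#' tabular text file (TSV or CSV; residue letter or 3-letter code in the
#' first column, one numeric column per descriptor dimension) or by the name
#' of a scale bundled with the package. The bundled default, `"zscale5"`, is
#' a five-dimensional z-scale-type set of lipophilicity/steric/electronic
#' property scores.
#'
#' @param source Name of a bundled scale (currently `"zscale5"`) or path to a
#'   readable table.
#' @return An object of class `descriptor_scale` with elements `name`,
#'   `dims`, and `values` (a 20 x d numeric matrix with residue rownames).
#' @export
load_scale <- function(source = "zscale5") {
  path <- source
  if (!file.exists(path)) {
    path <- system.file("extdata", "scales", paste0(source, ".tsv"),
                        package = "pepqsar")
    if (!nzchar(path)) stop(sprintf("unknown scale '%s': not a file and not bundled", source))
  }
  tab <- read_table_auto(path)
  if (ncol(tab) < 2L) stop("scale table needs a residue column plus >= 1 numeric column")
  res <- canonical_residue(as.character(tab[[1]]))
  if (anyDuplicated(res)) {
    stop(sprintf("duplicate residue row '%s' in scale table", res[duplicated(res)][1]))
  }
  missing <- setdiff(AA_ALPHABET, res)
  if (length(missing) > 0L) {
    stop(sprintf("scale table missing residue row(s): %s",
                 paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("scale table contains non-numeric or non-finite descriptor values")
  }
  rownames(vals) <- res
  vals <- vals[AA_ALPHABET, , drop = FALSE]
  structure(
    list(name = if (file.exists(source)) basename(source) else source,
         dims = ncol(vals), values = vals),
    class = "descriptor_scale"
  )
}

#' @export
print.descriptor_scale <- function(x, ...) {
  cat(sprintf("<descriptor_scale '%s': 20 residues x %d dimensions>\n",
              x$name, x$dims))
  invisible(x)
}

#' Build a descriptor scale from a matrix (mainly for tests)
#' @param values 20 x d numeric matrix, rownames the one-letter codes.
#' @param name Label for the scale.
#' @return A `descriptor_scale`.
#' @export
as_scale <- function(values, name = "custom") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || !setequal(rownames(values), AA_ALPHABET)) {
    stop("scale matrix must have the 20 standard residues as rownames")
  }
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite scale values")
  structure(list(name = name, dims = ncol(values),
                 values = values[AA_ALPHABET, , drop = FALSE]),
            class = "descriptor_scale")
}

#' Two-terminal encoding specification
#'
#' Variable-length peptides are mapped to fixed-length vectors by reading
#' `k_n` positions in from the N-terminus and `k_c` positions in from the
#' C-terminus; each position contributes the d descriptor values of the
#' residue found there. Positions beyond the peptide's length receive
#' `fill_value` in every descriptor dimension, and for peptides shorter than
#' `k_n + k_c` the two windows overlap, so a residue may be read by both.
#'
#' @param k_n Number of N-terminal positions (>= 1).
#' @param k_c Number of C-terminal positions (>= 0).
#' @param fill_value Value used for positions past the end of the peptide.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(k_n = 5L, k_c = 5L, fill_value = 0) {
  k_n <- as.integer(k_n); k_c <- as.integer(k_c)
  if (is.na(k_n) || k_n < 1L) stop("k_n must be >= 1")
  if (is.na(k_c) || k_c < 0L) stop("k_c must be >= 0")
  if (!is.finite(fill_value)) stop("fill_value must be finite")
  structure(list(k_n = k_n, k_c = k_c, fill_value = fill_value),
            class = "encoding_spec")
}

#' Encode one peptide as a fixed-length descriptor vector
#'
#' Layout is `[N-pos 1 .. N-pos k_n, C-pos 1 .. C-pos k_c]` where N-pos i is
#' the descriptor vector of residue i counted from the N-terminus and C-pos j
#' that of residue j counted from the C-terminus (C-pos 1 = last residue).
#'
#' @param seq Canonical peptide string (see [validate_sequence()]).
#' @param spec An [encoding_spec()].
#' @param scale A [load_scale()] descriptor scale.
#' @return Numeric vector of length `(k_n + k_c) * d`.
#' @export
#' @examples
#' sc <- load_scale()
#' length(encode_peptide("WY", encoding_spec(5, 5), sc))  # 50
encode_peptide <- function(seq, spec, scale) {
  seq <- validate_sequence(seq)
  stopifnot(inherits(spec, "encoding_spec"), inherits(scale, "descriptor_scale"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(chars)
  d <- scale$dims
  fill_row <- rep(spec$fill_value, d)
  block <- function(idx) {
    # idx holds 1-based residue positions; NA marks positions past the end
    out <- matrix(fill_row, nrow = length(idx), ncol = d, byrow = TRUE)
    ok <- !is.na(idx)
    if (any(ok)) out[ok, ] <- scale$values[chars[idx[ok]], , drop = FALSE]
    out
  }
  n_idx <- ifelse(seq_len(spec$k_n) <= len, seq_len(spec$k_n), NA_integer_)
  c_idx <- if (spec$k_c > 0L) {
    ifelse(seq_len(spec$k_c) <= len, len - seq_len(spec$k_c) + 1L, NA_integer_)
  } else integer(0)
  as.numeric(t(rbind(block(n_idx), if (spec$k_c > 0L) block(c_idx))))
}

#' Encode a set of peptides into a design matrix
#'
#' @param peptides Character vector of sequences; row order is preserved and
#'   duplicates are kept.
#' @inheritParams encode_peptide
#' @return Numeric matrix, one row per peptide, with the sequences as
#'   rownames-free `attr(, "sequence")` index.
#' @export
encode_set <- function(peptides, spec, scale) {
  if (length(peptides) == 0L) stop("no peptides to encode")
  rows <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    rows[[i]] <- tryCatch(
      encode_peptide(peptides[[i]], spec, scale),
      error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  X <- do.call(rbind, rows)
  attr(X, "sequence") <- vapply(peptides, validate_sequence, character(1),
                                USE.NAMES = FALSE)
  X
}

# map 3-letter codes (Table-1 style) or 1-letter codes to 1-letter
canonical_residue <- function(x) {
  x <- trimws(x)
  three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  out <- ifelse(nchar(x) == 1L, toupper(x),
                unname(three[paste0(toupper(substr(x, 1, 1)),
                                    tolower(substr(x, 2, 3)))]))
  if (anyNA(out)) {
    stop(sprintf("unrecognized residue code '%s'", x[is.na(out)][1]))
  }
  out
}
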