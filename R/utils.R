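# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA of length n with the given A,C,G,T probabilities.
random_dna <- function(n, base_composition) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = base_composition), collapse = "")
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer uniform draw(s) in [lo, hi], vectorized over n.
rint <- function(n, lo, hi) {
  if (any(hi < lo)) stop("empty integer range")
  lo + floor(runif(n) * (hi - lo + 1L))
}

# All 4^k k-mers in Biostrings column order (A < C < G < T, first position
# slowest) so names line up with oligonucleotideFrequency() output.
all_kmers <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

# Precedence order used wherever overlapping region classes must resolve
# to a single class for a nucleotide.
REGION_PRECEDENCE <- c("ncRNA", "ORF", "UTR5", "UTR3", "intron")

EXONIC_CLASSES <- c("ORF", "UTR5", "UTR3")
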