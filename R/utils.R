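# internal helpers shared across modules

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# reverse complement of a plain DNA character string (ACGTN, any case)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement of a character vector of single bases
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# split an in-frame DNA/RNA string into codons (RNA alphabet, uppercase)
codon_split <- function(cds) {
  cds <- chartr("acgtun", "ACGUUN", cds)
  cds <- gsub("T", "U", cds, fixed = TRUE)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# circular 1-based index arithmetic
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

# extract a substring from a circular sequence; start..end may wrap past len
circular_substr <- function(seq, start, end, len = nchar(seq)) {
  start <- wrap_pos(start, len)
  end <- wrap_pos(end, len)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, len), substr(seq, 1L, end))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
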