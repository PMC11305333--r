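# Low-level sequence helpers shared by the simulators and the variant
# classifier. Sequences are plain upper-case character strings on the
# forward strand; Biostrings is used for alphabet-aware operations.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Codon table. Stops translate to "*".
.codon_env <- new.env(parent = emptyenv())

#' @noRd
genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    .codon_env$code <- Biostrings::GENETIC_CODE
  }
  .codon_env$code
}

#' Translate a coding DNA string
#'
#' Codon-by-codon translation using the standard genetic code; stop codons
#' become `"*"`. Trailing bases that do not fill a codon are ignored.
#'
#' @param x coding-strand DNA string.
#' @param to_first_stop if `TRUE`, return the peptide up to (excluding) the
#'   first stop codon.
#' @return amino-acid string.
#' @export
translate_cds <- function(x, to_first_stop = FALSE) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  p <- paste(aa, collapse = "")
  if (to_first_stop) {
    stop_at <- regexpr("*", p, fixed = TRUE)
    if (stop_at > 0L) p <- substr(p, 1L, stop_at - 1L)
  }
  p
}

# Single-base substitution tables per sense codon, built once:
# for every codon, the substitutions that are synonymous, missense
# (non-stop), or nonsense (create a stop).
#' @noRd
codon_sub_table <- function() {
  if (!is.null(.codon_env$subs)) return(.codon_env$subs)
  code <- genetic_code()
  codons <- names(code)
  out <- list()
  for (cod in codons) {
    rows <- list()
    for (k in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cod, k, k))) {
        mut <- cod
        substr(mut, k, k) <- b
        kind <- if (code[[mut]] == code[[cod]]) "synonymous"
          else if (code[[mut]] == "*") "nonsense"
          else "missense"
        rows[[length(rows) + 1L]] <- data.frame(
          pos = k, base = b, mut_codon = mut, kind = kind,
          stringsAsFactors = FALSE)
      }
    }
    out[[cod]] <- do.call(rbind, rows)
  }
  .codon_env$subs <- out
  out
}

#' @noRd
stop_codons <- function() {
  code <- genetic_code()
  names(code)[code == "*"]
}

#' @noRd
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

# Seed handling: every public generator takes an integer seed and restores
# the caller's RNG state on exit, so generators are pure functions of
# their arguments.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this keeps ranges safe.
#' @noRd
samp_range <- function(a, b, n = 1L) {
  v <- seq.int(a, b)
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

#' @noRd
samp_one <- function(x) {
  if (length(x) == 1L) x else sample(x, 1L)
}
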