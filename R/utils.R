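#' @import Biostrings
#' @importFrom stats median sd cor cor.test p.adjust rnorm runif setNames
#'   hclust cutree dist lm coef phyper na.omit .lm.fit
#' @importFrom utils read.delim write.table combn adist
NULL

# Substitution matrix over {A,C,G,T,N}: N never matches anything (including N).
.sub_matrix <- function(match = 1L, mismatch = -1L) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(as.numeric(mismatch), 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

.check_dna <- function(x, what = "sequence") {
  if (length(x) == 0L || any(is.na(x)) || any(!nzchar(x))) {
    stop(what, " must be a non-empty DNA sequence", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  toupper(x)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic local RNG: run `expr` under `seed` without disturbing the
# caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage seed from a root seed, kept within 32-bit integer range.
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919L) %% 2147483587)
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute `k` random positions (never producing the original base).
.mutate_subs <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

.iso_date <- function(x) format(x, "%Y-%m-%d")
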