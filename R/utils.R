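DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_dna <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[ACGT]+$", x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' The global RNG state is saved, the seed set, the expression evaluated, and
#' the previous state restored, so seeded simulation calls do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from a master seed and a string key; stays below
# 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, key) {
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u)) %% 1e6
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 + h) %% 2147483647)
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Per-string Hamming mismatches against a single target of equal width.
string_mismatches <- function(strings, target) {
  tl <- nchar(target)
  if (length(strings) == 0) return(integer(0))
  stopifnot(all(nchar(strings) == tl))
  tchars <- strsplit(target, "")[[1]]
  m <- matrix(unlist(strsplit(strings, ""), use.names = FALSE), nrow = tl)
  as.integer(colSums(m != tchars))
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
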