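# Internal helpers shared across modules.

# Deterministic string hash into [1, 2^31 - 2]; pure double arithmetic kept
# below 2^53 so results are platform-stable.  Used to derive per-dataset
# seeds from condition fields and a master seed.
stable_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Frobenius norm squared.
fnorm2 <- function(M) sum(M * M)

# Normalize columns of a matrix to unit Euclidean norm (zero columns error).
unit_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  if (any(nrm == 0)) stop("cannot normalize a zero column")
  sweep(M, 2L, nrm, "/")
}

# Number of nonzeros per component implied by a target sparsity proportion.
ps_to_cardinality <- function(ps, J) {
  r <- round((1 - ps) * J)
  max(1L, min(J, as.integer(r)))
}
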