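# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers the
# session's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic, platform-independent lexicographic sort (C locale).
sort_c <- function(x) sort(unique(x), method = "radix")

# Stable 31-bit polynomial string hash used to derive independent per-key
# seeds from a base seed.  Order-independent grid imputation depends on
# this being a pure function of the key string.  Arithmetic stays in
# doubles (exact below 2^53) and is reduced mod a prime < 2^31.
hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(base_seed, key) {
  as.integer((as.double(base_seed) + hash31(key)) %% 2147483629)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

# Pearson correlation that returns NA (no warning) when either vector is
# constant; callers flag these as "undefined" rather than erroring.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Population variance (divide by n); the variance convention recorded in
# evaluation output metadata.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sum((x - mean(x))^2) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

combo_id <- function(species, tissue) paste(species, tissue, sep = "\t")
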