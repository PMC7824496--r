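# internal helpers: deterministic seed derivation and scoped RNG use

# polynomial rolling hash of a string, kept under 2^31 (R integers are 32-bit)
.str_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# derive a reproducible sub-seed from a master seed plus arbitrary labels;
# labels are hashed so results do not depend on call order
derive_seed <- function(seed, ...) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + .str_hash(...)) %%
               2147483629)
}

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# unordered-pair seed: symmetric in (a, b) so p(A,B) == p(B,A)
.pair_seed <- function(seed, a, b) {
  key <- paste(sort(c(a, b)), collapse = "\r")
  derive_seed(seed, key)
}

.stop_if_not_named_numeric <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || anyNA(names(x)))
    stop(what, " must be a named numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
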