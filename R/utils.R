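# Internal helpers: classed conditions and seed management.

# Signal a classed error. Every condition carries "musadicho_error" plus a
# specific subclass so callers (and tests) can branch on the failure mode.
md_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "musadicho_error")))
}

md_check <- function(ok, msg, class = "musadicho_invalid_argument") {
  if (!isTRUE(ok)) md_stop(msg, class)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state so
# generators never perturb the global random stream.
with_seed <- function(seed, code) {
  md_check(is_count(seed, min = 0L) || is_count(-seed, min = 0L),
           "`seed` must be a single integer")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed (< 2^31) from a master seed, a stage label
# and an index, so pipeline stages and per-plant simulations can be rerun in
# isolation.
derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 8191 + index * 131071) %%
               2147483629)
}
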