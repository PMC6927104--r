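# internal helpers shared across the package

# validation errors get a condition class so the CLI can map them to exit code 2
stop_cde <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("cdemapr_error", "error", "condition")))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# fixed attribute order used everywhere similarities are vectorised
cde_attributes <- function() {
  c("long_name", "object_class", "property", "value_domain_long_name",
    "representation_term", "question_text")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
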