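# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# derive a child seed from a base seed and a stream label, kept < 2^31
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * 131) + as.numeric(seed) * 7919
  as.integer(s %% 2147483629)
}

# wholesale top-level merge of a user spec over defaults: any supplied key
# replaces the default entirely (modifyList would silently drop unnamed
# nested list elements, e.g. lists of blob or nucleus specs)
merge_spec <- function(defaults, spec) {
  stopifnot(is.list(spec))
  bad <- setdiff(names(spec), names(defaults))
  if (length(bad))
    stop("unknown spec field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaults[names(spec)] <- spec
  defaults
}
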