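# Internal validation helpers. All user-facing validation failures raise a
# condition of class "pp_validation_error" so callers and drivers can
# distinguish bad input (exit 2 semantics) from unexpected failure.

pp_stop <- function(..., call = sys.call(-1)) {
  stop(errorCondition(paste0(...), class = c("pp_validation_error", "error"),
                      call = call))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    pp_stop("'", name, "' must be a single non-missing number")
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) pp_stop("'", name, "' must lie in [0, 1], got ", x)
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  assert_scalar_number(x, name)
  if (x != as.integer(x)) pp_stop("'", name, "' must be an integer, got ", x)
  if (positive && x < 1) pp_stop("'", name, "' must be >= 1, got ", x)
  if (!positive && x < 0) pp_stop("'", name, "' must be >= 0, got ", x)
  invisible(as.integer(x))
}

# Counter-based sub-seed: patient/sample i always receives the same stream
# for a given base seed, so enlarging a cohort never reshuffles earlier
# records. Kept below 2^31 - 1 (R integer range).
sub_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + counter * 16807) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
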