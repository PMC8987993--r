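# internal helpers shared across modules

.assert <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
}

# sex is carried as "male"/"female" in participant tables and encoded
# numerically downstream as female = 0, male = 1
.sexToNumeric <- function(sex) {
  if (is.numeric(sex)) {
    .assert(all(sex %in% c(0, 1)), "numeric sex must be coded 0/1")
    return(as.numeric(sex))
  }
  s <- tolower(as.character(sex))
  .assert(all(s %in% c("male", "female")),
          "sex must be 'male'/'female' (or 0/1)")
  as.numeric(s == "male")
}

# stage seeds derived from one master seed; kept well below 2^31
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

.checkFinite <- function(x, what) {
  .assert(!anyNA(x) && all(is.finite(x)), "%s must be finite with no NA", what)
}
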