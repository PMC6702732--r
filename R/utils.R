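#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree pchisq rbinom runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# size range of the strand-specific profile, in nt
PROFILE_SIZES <- 15:35

# column labels of the 42-cell profile vector: positive strand 15..35,
# then negative strand 15..35
profile_cell_names <- function() {
  c(paste0("p", PROFILE_SIZES), paste0("m", PROFILE_SIZES))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_virosift <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_virosift(...)
  invisible(TRUE)
}

# reverse complement of an ACGTN string (delegates to Biostrings so N and
# case handling match the alignment code)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# restore RNG state on exit so seeded generators do not perturb the
# caller's random stream
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number, got %s", format(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
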