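# Internal helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

GROUPS <- c("middle_aged", "elderly")
STATES <- c("eyes_open", "eyes_closed", "wm_task")

# Default 8-electrode montage (10-20 positions, frontal/central/parietal/occipital).
DEFAULT_CHANNELS <- c("FP1", "FP2", "C3", "C4", "P7", "P8", "O1", "O2")

stop_input <- function(...) {
  stop(structure(class = c("eegnetage_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("eegnetage_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_group <- function(group) {
  if (!is.character(group) || length(group) != 1L || !group %in% GROUPS)
    stop_input("'group' must be one of: ", paste(GROUPS, collapse = ", "))
  group
}

check_state <- function(state) {
  if (!is.character(state) || length(state) != 1L || !state %in% STATES)
    stop_input("'state' must be one of: ", paste(STATES, collapse = ", "))
  state
}

# Deterministic 31-bit child seed from a master seed and a stream label.
# Multiplicative string hash (polynomial in 31, Knuth-style mix) so child
# streams do not depend on generation order. Plain integer arithmetic on
# doubles; all intermediates < 2^52 so the result is exact.
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) {
    h <- (h * 31 + cp) %% 2147483647
    h <- (h * 48271) %% 2147483647  # MINSTD step keeps streams well mixed
  }
  as.integer(h)
}

# Run expr with a local RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
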