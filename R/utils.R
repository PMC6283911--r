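# shared validation helpers

# 20 standard residues plus the degenerate codes we tolerate
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTRA <- c("X", "B", "Z", "U")
AA_ALLOWED <- c(AA_STANDARD, AA_EXTRA)
AA_EXT <- AA_ALLOWED

# average amino-acid composition (Swiss-Prot-like, rounded); used as the
# default background for profile emissions and the proteome simulator
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0663, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

stop_earminer <- function(msg, class = "earminer_error") {
  abort(msg, class = c(class, "earminer_error"))
}

assert_aa_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop_earminer(sprintf("%s must be a non-empty string", what))
  }
  bad <- stringr::str_locate(toupper(seq), sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")))
  if (!is.na(bad[1, 1])) {
    stop_earminer(sprintf(
      "invalid residue '%s' at position %d of %s",
      substr(seq, bad[1, 1], bad[1, 1]), bad[1, 1], what
    ), class = "earminer_alphabet_error")
  }
  invisible(toupper(seq))
}

# normalise a residue background vector to the 20 standard residues
normalise_background <- function(background) {
  if (is.null(background)) background <- AA_BACKGROUND
  if (is.null(names(background)) || !all(AA_STANDARD %in% names(background))) {
    stop_earminer("background must be a named vector covering the 20 standard residues")
  }
  background <- background[AA_STANDARD]
  if (any(background <= 0)) stop_earminer("background frequencies must be positive")
  background / sum(background)
}

# deterministic RNG scope: everything stochastic funnels through here
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# derive a child seed from a master seed (keeps values inside 32-bit range)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 1000003 + as.double(p)) %% 2147483629
  as.integer(x) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
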