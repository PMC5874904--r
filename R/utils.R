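# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that a
# given seed yields an identical result regardless of surrounding calls.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Amino-acid alphabet accepted throughout: the 20 standard residues plus X.
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

assert_aa <- function(sequences, ids) {
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", toupper(sequences))
  if (any(bad)) {
    stop("illegal amino-acid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

is_unknown_host <- function(x) {
  is.na(x) | !nzchar(trimws(x)) | tolower(trimws(x)) == "unknown"
}

# Canonical host-genus token: trimmed, case-folded to title case so that
# inconsistently cased metadata compares equal.
normalize_genus <- function(x) {
  x <- trimws(x)
  out <- ifelse(is_unknown_host(x), NA_character_,
                paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2))))
  out
}
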