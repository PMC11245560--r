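# internal helpers shared across modules

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# random sequence of length n as a single string
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute bases at `pos` (1-based) of `seq` with a uniformly chosen
# different base; returns list(seq, pos, from, to)
mutate_seq <- function(seq, pos) {
  n <- length(pos)
  if (n == 0L) return(list(seq = seq, pos = integer(), from = character(), to = character()))
  raw <- charToRaw(seq)
  raw_bases <- charToRaw(paste(DNA_BASES, collapse = ""))
  idx <- match(raw[pos], raw_bases)
  new_idx <- ((idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  from <- DNA_BASES[idx]
  to <- DNA_BASES[new_idx]
  raw[pos] <- raw_bases[new_idx]
  list(seq = rawToChar(raw), pos = pos, from = from, to = to)
}

# positions hit by a per-bp Bernoulli(rate) process on a sequence of length L
draw_mutation_positions <- function(L, rate) {
  n <- rbinom(1L, L, rate)
  if (n == 0L) return(integer())
  sort(sample.int(L, n))
}

# positions at which two equal-length strings differ
string_mismatch_positions <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b))
}

# reverse complement for a character vector of sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) stop(sprintf("'%s' must be a single number in %s%s, %s%s",
                        name,
                        if (closed_lower) "[" else "(", format(lower),
                        format(upper), if (closed_upper) "]" else ")"),
                call. = FALSE)
  invisible(x)
}
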