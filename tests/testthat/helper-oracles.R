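# Independent oracles, kept free of the package's own code paths.

# Textbook dynamic-programming Levenshtein, row by row.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- numeric(length(y) + 1)
    cur[1] <- i
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  as.integer(prev[length(y) + 1])
}

# random strings over a reduced alphabet
random_strings <- function(n, max_len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, sample(0:max_len, 1), replace = TRUE),
           collapse = "")
  }, character(1))
}

# small clone table constructor for hand-arithmetic tests
clone_tbl <- function(copies, sample_id = "s1",
                      v = paste0("TRBV", seq_along(copies)),
                      j = "TRBJ1-1",
                      cdr3 = paste0("CASS", LETTERS[seq_along(copies)], "F")) {
  tibble::tibble(
    sample_id = sample_id, v_call = v, j_call = j, cdr3_aa = cdr3,
    copies = as.integer(copies), frequency = copies / sum(copies)
  )
}
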