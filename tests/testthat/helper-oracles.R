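# Shared fixtures and independent oracles for the test suite.

germ <- read_germline_reference()
heavy <- germ[germ$chain == "heavy", ]

# Pure-R all-pairs reimplementation of the singleton-rescue clustering,
# used as an oracle against the package implementation.
brute_clonotype <- function(keys, h) {
  ab <- keys[keys$count >= 2L, ]
  si <- keys[keys$count == 1L, ]
  if (h == 0L || nrow(ab) == 0L || nrow(si) == 0L) {
    return(keys[order(-keys$count, keys$key), ])
  }
  counts <- ab$count
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  keep <- rep(TRUE, nrow(si))
  for (i in seq_len(nrow(si))) {
    best <- NA_integer_
    for (j in seq_len(nrow(ab))) {
      if (nchar(si$key[i]) != nchar(ab$key[j])) next
      if (ham(si$key[i], ab$key[j]) <= h) {
        if (is.na(best) ||
            ab$count[j] > ab$count[best] ||
            (ab$count[j] == ab$count[best] && ab$key[j] < ab$key[best])) {
          best <- j
        }
      }
    }
    if (!is.na(best)) {
      counts[best] <- counts[best] + 1L
      keep[i] <- FALSE
    }
  }
  out <- rbind(data.frame(key = ab$key, count = counts),
               data.frame(key = si$key[keep],
                          count = rep(1L, sum(keep))))
  out[order(-out$count, out$key), ]
}

# Random key-count tables for property tests: clustered around a few motifs
# so Hamming neighbours actually occur.
random_key_table <- function(n_keys, alphabet = c("A", "C", "D", "E"),
                             len = 5L) {
  motifs <- replicate(max(2L, n_keys %/% 10L),
                      paste(sample(alphabet, len, replace = TRUE), collapse = ""))
  keys <- head(unique(vapply(seq_len(n_keys * 2L), function(i) {
    m <- strsplit(sample(motifs, 1L), "")[[1]]
    pos <- sample.int(len, sample(0:2, 1L))
    m[pos] <- sample(alphabet, length(pos), replace = TRUE)
    paste(m, collapse = "")
  }, "")), n_keys)
  tibble::tibble(key = keys,
                 count = sample(c(1L, 1L, 1L, 2L, 3L, 8L),
                                length(keys), replace = TRUE))
}

# A tiny clean annotation set built from a known repertoire; memoised so
# several test files can share it.
small_clean_annotations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- repertoire_spec(n_clones = 400, chain = "heavy", seed = 101,
                              nonproductive_fraction = 0)
      clones <- generate_repertoire(spec, heavy)
      reads <- simulate_reads(clones, 1500, sub_rate = 0, seed = 101)
      ann <- annotate_reads(reads, heavy)
      cache <<- list(spec = spec, clones = clones, reads = reads, ann = ann)
    }
    cache
  }
})
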