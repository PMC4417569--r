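# Shared fixtures and helpers; all inputs are generated in code.

# The five example reads used throughout the documentation: their trie has
# five leaves and the A-subtree groups the first three.
fig_strings <- c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC")

# Six short reads whose work estimates are 6, 10, 10, 6, 6, 10.
sched_strings <- c("ACC", "AATC", "CGTC", "TTA", "TGA", "CCAT")

# canonical sortable representation of an overlap record set (file-order ids)
rec_key <- function(d) {
  sort(paste(d$query_orig, d$target_orig, d$length, sep = ":"))
}

# random reads with lengths drawn uniformly from a range
rand_reads <- function(k, len_range = c(20L, 200L)) {
  lens <- sample(len_range[1]:len_range[2], k, replace = TRUE)
  read_set(vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1)))
}

# pick a node index by predicate, failing loudly if not unique
node_where <- function(trie, pred) {
  idx <- which(pred(trie))
  stopifnot(length(idx) == 1L)
  idx
}
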