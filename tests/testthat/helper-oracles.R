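# Independent brute-force oracles used to freeze expected values.
# These work purely on strings and never call the package's canonical-form
# or microhomology code.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_edit <- function(s, a, b, ins = "") {
  paste0(substr(s, 1, a), ins, substr(s, b + 1, nchar(s)))
}

# minimal-del_start equivalent edit with the same deletion/insertion
# lengths producing the identical mutated string
brute_canonical <- function(s, a, b, ins = "") {
  m <- apply_edit(s, a, b, ins)
  L <- nchar(ins)
  D <- b - a
  n <- nchar(s)
  for (a2 in 0:(n - D)) {
    ins2 <- substr(m, a2 + 1, a2 + L)
    if (apply_edit(s, a2, a2 + D, ins2) == m)
      return(list(a = a2, b = a2 + D, ins = ins2))
  }
  stop("no equivalent edit found")  # unreachable
}

# number of deletion windows of the same size producing the identical
# mutated string
brute_window_count <- function(s, a, b) {
  m <- apply_edit(s, a, b)
  D <- b - a
  n <- nchar(s)
  sum(vapply(0:(n - D), function(a2)
    apply_edit(s, a2, a2 + D) == m, TRUE))
}

# a toy target: 23-mer with PAM at 20, cut at 17, distal flank 'T' and
# proximal flank 'C'
toy_target <- function(distal = "T", proximal = "C") {
  s <- "GATTACAGGATCCTAGTCATTGG"
  substr(s, 17, 17) <- distal
  substr(s, 18, 18) <- proximal
  target_site("toy", s, 0L, 20L)
}

# a wide target with enough context for full candidate enumeration
wide_target <- function(seed = 42L, id = "W1") {
  set.seed(seed)
  s <- paste0(random_seq(30), random_seq(20), random_seq(1), "GG",
              random_seq(30))
  target_site(id, s, 30L, 50L)
}

# tiny screen dataset built by hand from explicit count rows
make_counts <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(cell_line = r[[1]], replicate = as.integer(r[[2]]),
               timepoint = r[[3]], target_id = r[[4]], outcome = r[[5]],
               reads = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
}

adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  (a - expected) / ((b + cc) / 2 - expected)
}
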