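# Independent oracles used to cross-check the package implementations.
# These deliberately take the naive route (per-bond loops, explicit polygon
# vertices) rather than sharing code with the package.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Brute-force cleavage-site prediction: evaluate every clause of every
# enzyme at every bond by direct window inspection of the rule TSV.
oracle_sites <- function(sequence, enzymes) {
  tab <- read.delim(system.file("extdata", "cleavage_rules.tsv",
                                package = "allerscreen"),
                    stringsAsFactors = FALSE)
  offs <- c("P4" = -3, "P3" = -2, "P2" = -1, "P1" = 0,
            "P1'" = 1, "P2'" = 2, "P3'" = 3, "P4'" = 4)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2) return(integer(0))
  clause_sat <- function(cl, b) {
    for (i in seq_len(nrow(cl))) {
      p <- b + offs[[cl$slot[i]]]
      if (p < 1 || p > n) return(FALSE)
      inset <- grepl(res[p], cl$residues[i], fixed = TRUE)
      if (cl$mode[i] == "allowed" && !inset) return(FALSE)
      if (cl$mode[i] == "forbidden" && inset) return(FALSE)
    }
    TRUE
  }
  cuts <- integer(0)
  for (b in seq_len(n - 1)) {
    for (enz in enzymes) {
      sub <- tab[tab$enzyme == enz, ]
      cut <- FALSE
      blocked <- FALSE
      for (cid in unique(sub$clause)) {
        cl <- sub[sub$clause == cid, ]
        if (clause_sat(cl, b)) {
          if (cl$action[1] == "cut") cut <- TRUE else blocked <- TRUE
        }
      }
      if (cut && !blocked) {
        cuts <- c(cuts, b)
        break
      }
    }
  }
  cuts
}

# Shoelace area of the explicit radar polygon (closed over all 16 axes).
shoelace_radar_area <- function(r) {
  theta <- (seq_along(r) - 1) * 2 * pi / length(r)
  x <- r * cos(theta)
  y <- r * sin(theta)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# The 24 reference survivors of the simulated milk digestion, by parent.
reference_survivors <- function() {
  fx <- load_reference_data()
  fx$is_peptides
}
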