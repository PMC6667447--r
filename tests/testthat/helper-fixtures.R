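# Shared small fixtures, built in code.

# Hand-built site table: nGenes genes, L coding positions each, all on one
# chromosome, with simple deterministic features.
tinySiteTable <- function(nGenes = 2, L = 6, bg = TRUE, fn = TRUE) {
  rows <- list()
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  refs <- rep(c("C", "T", "A", "G"), length.out = L)
  pos0 <- 0L
  for (g in seq_len(nGenes)) {
    for (i in seq_len(L)) {
      ref <- refs[i]
      c5 <- "A"
      c3 <- if (i %% 2 == 0) "G" else "T"
      for (alt in alts[[ref]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = paste0("gene", g), chrom = "chr1",
          pos = pos0 + i, ref = ref, alt = alt,
          context5 = c5, context3 = c3, stringsAsFactors = FALSE)
      }
    }
    pos0 <- pos0 + L + 10L
  }
  s <- do.call(rbind, rows)
  s$mutation_type <- classifyMutationType(s$ref, s$alt, s$context5,
                                          s$context3)
  # first position of each gene synonymous (all three alts), rest NS
  s$impact <- ifelse(s$pos %% (L + 10L) %in% c(1L, 2L), "S", "NS")
  bgm <- if (bg) {
    cbind(expr = rep(rep(c(0.5, -0.5), length.out = nGenes),
                     each = 3L * L))
  } else NULL
  fnm <- if (fn) {
    m <- matrix(0, nrow(s), 2, dimnames = list(NULL, c("LoF", "CONS")))
    m[s$impact == "NS" & s$alt == "T", "LoF"] <- 1
    m[s$impact == "NS" & s$pos %% 3 == 0, "CONS"] <- 1
    m
  } else NULL
  SiteTable(s, bgm, fnm)
}

# A moderate simulated data set shared by several test files (cached).
.simCache <- new.env()
sharedSimulation <- function() {
  if (is.null(.simCache$data)) {
    st <- makeGenomeFixture(250, 400, seed = 401)
    genes <- geneIds(st)
    roles <- c(rep("TSG", 8), rep("OG", 8))
    names(roles) <- genes[1:16]
    cfg <- simConfig(roles = roles, seed = 402)
    sim <- simulateCounts(st, cfg)
    .simCache$data <- list(sites = st, sim = sim, cfg = cfg,
                           genes = genes, roles = roles)
  }
  .simCache$data
}

writeTempMutations <- function(df, comment = FALSE) {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "w")
  if (comment) writeLines("# generated fixture", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}
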