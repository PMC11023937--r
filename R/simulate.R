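#' Simulation parameters
#'
#' The generative law for nuclei and molecular complexes. Non-singleton
#' cluster sizes follow a mixture: size 2 with probability `p2` (default
#' 0.7226, the size-2 fraction observed among non-singleton DNA-only clusters
#' in deep ensemble data) and a truncated power law `P(k) ~ k^-size_gamma`
#' over sizes 3..`max_cluster_size` otherwise. Intra-complex genomic
#' distances follow a truncated power law with exponent `distance_alpha` on
#' `[d_min, d_max]`, confined to one chromosome arm.
#'
#' @param n_cells Number of nuclei.
#' @param complexes_per_cell Molecular complexes per nucleus.
#' @param p2 Probability that a non-singleton complex has exactly 2 members.
#' @param size_gamma Power-law exponent for sizes >= 3.
#' @param max_cluster_size Upper truncation of the size law.
#' @param singleton_rate Fraction of complexes with a single member.
#' @param rna_fraction Per-member probability of being an RNA molecule.
#' @param distance_alpha Intra-complex distance power-law exponent.
#' @param d_min,d_max Distance truncation in bp.
#' @param frag_length Integer range (min, max) of insert lengths.
#' @param xist_rate Per-complex probability, in female cells, of being an
#'   XIST-attachment complex (>= 1 XIST RNA read, DNA on chrX).
#' @param duplicate_rate Expected PCR copies per molecule (Poisson mean).
#' @param female_fraction Fraction of cells simulated as female.
#' @param sample_ages Chronological ages of the simulated donors; cells are
#'   split evenly across donors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200L, complexes_per_cell = 60L,
                       p2 = 0.7226, size_gamma = 2.5, max_cluster_size = 100L,
                       singleton_rate = 0.1, rna_fraction = 0.2,
                       distance_alpha = 1.0, d_min = 1000, d_max = 2e5,
                       frag_length = c(30L, 60L), xist_rate = 0.15,
                       duplicate_rate = 0, female_fraction = 0.5,
                       sample_ages = c(62, 71, 80, 89)) {
  cfg <- as.list(environment())
  probs <- c(p2, singleton_rate, rna_fraction, xist_rate, female_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Truncated power-law sampler
#'
#' Draws from density `p(x) ~ x^-alpha` on `[xmin, xmax]` by inverse CDF.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 0; `alpha = 1` handled analytically).
#' @param xmin,xmax Support bounds.
#' @return Numeric vector of length `n`.
#' @export
rpower_law <- function(n, alpha, xmin, xmax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    xmin * (xmax / xmin)^u
  } else {
    a1 <- 1 - alpha
    (xmin^a1 + u * (xmax^a1 - xmin^a1))^(1 / a1)
  }
}

.sample_sizes <- function(n, cfg) {
  sizes <- integer(n)
  singleton <- runif(n) < cfg$singleton_rate
  pair <- !singleton & runif(n) < cfg$p2
  sizes[singleton] <- 1L
  sizes[pair] <- 2L
  n_multi <- sum(!singleton & !pair)
  if (n_multi > 0) {
    ks <- 3:cfg$max_cluster_size
    pk <- ks^(-cfg$size_gamma)
    sizes[!singleton & !pair] <- sample(ks, n_multi, replace = TRUE,
                                        prob = pk / sum(pk))
  }
  sizes
}

#' Simulate ground-truth nuclei and molecular complexes
#'
#' Every complex belongs to exactly one cell; within a cell, complexes receive
#' distinct (GEM, I7) barcode pairs so the cluster key recovers the complex
#' partition exactly. Molecule-level truth (coordinates, gene of origin,
#' duplicate links) is retained for round-trip testing.
#'
#' @param ref A [make_reference()] object.
#' @param params A [sim_config()].
#' @param seed Integer seed.
#' @param tables Barcode whitelists ([music_barcode_tables()]).
#' @return A `music_ground_truth` list with tibbles `cells`, `complexes`,
#'   `molecules`, `reads` (molecule occurrences incl. PCR copies), plus the
#'   `tables` and `ref` used.
#' @export
simulate_ground_truth <- function(ref, params = sim_config(), seed = 1L,
                                  tables = music_barcode_tables(seed = seed)) {
  stopifnot(inherits(ref, "music_reference"), inherits(params, "sim_config"))
  withr_seed(seed + 1L)
  cfg <- params
  chroms <- ref$chromosomes
  n_cells <- cfg$n_cells

  # unique cell-barcode triples
  space <- length(tables$cb1) * length(tables$cb2) * length(tables$cb3)
  if (n_cells > space) stop("more cells than barcode combinations")
  combo <- sample(space, n_cells) - 1L
  cells <- tibble(
    cell_id = sprintf("C%04d", seq_len(n_cells)),
    species = sample(unique(chroms$species), n_cells, replace = TRUE),
    sex = if_else(runif(n_cells) < cfg$female_fraction, "F", "M"),
    cell_type = sample(ref$config$cell_types, n_cells, replace = TRUE),
    sample_id = paste0("S", 1 + (seq_len(n_cells) - 1L) %% length(cfg$sample_ages)),
    age = cfg$sample_ages[1 + (seq_len(n_cells) - 1L) %% length(cfg$sample_ages)],
    ageing_factor = runif(n_cells),
    cb1 = as.integer(combo %% 96L) + 1L,
    cb2 = as.integer((combo %/% 96L) %% 96L) + 1L,
    cb3 = as.integer(combo %/% (96L * 96L)) + 1L)

  n_cplx <- n_cells * cfg$complexes_per_cell
  cplx_cell <- rep(seq_len(n_cells), each = cfg$complexes_per_cell)
  # distinct (gem, i7) per complex within a cell
  gi_space <- length(tables$gem) * length(tables$i7)
  if (cfg$complexes_per_cell > gi_space) stop("complex-barcode space exhausted")
  gi <- unlist(lapply(seq_len(n_cells), function(i)
    sample(gi_space, cfg$complexes_per_cell) - 1L))
  sizes <- .sample_sizes(n_cplx, cfg)

  complexes <- tibble(
    complex_id = sprintf("X%06d", seq_len(n_cplx)),
    cell_id = cells$cell_id[cplx_cell],
    species = cells$species[cplx_cell],
    sex = cells$sex[cplx_cell],
    gem = as.integer(gi %% length(tables$gem)) + 1L,
    i7 = as.integer(gi %/% length(tables$gem)) + 1L,
    size = sizes)
  complexes$is_xist <- complexes$sex == "F" & runif(n_cplx) < cfg$xist_rate

  genes_by_chrom <- split(ref$genes, ref$genes$chrom)
  mol_l <- vector("list", n_cplx)
  for (i in seq_len(n_cplx)) {
    sp <- complexes$species[i]
    sp_chroms <- chroms[chroms$species == sp, ]
    if (complexes$is_xist[i]) {
      ci <- which(sp_chroms$is_x)[1]
      if (is.na(ci)) { complexes$is_xist[i] <- FALSE; ci <- sample(nrow(sp_chroms), 1L, prob = sp_chroms$length) }
    } else {
      ci <- sample(nrow(sp_chroms), 1L, prob = sp_chroms$length)
    }
    chrom <- sp_chroms$chrom[ci]; L <- sp_chroms$length[ci]
    arm_b <- sp_chroms$arm_boundary[ci]
    S <- complexes$size[i]
    is_rna <- runif(S) < cfg$rna_fraction
    if (complexes$is_xist[i] && !any(is_rna)) is_rna[1] <- TRUE
    n_dna <- sum(!is_rna)
    # DNA fragment coordinates: anchor + power-law offsets within one arm
    arm <- if (runif(1) < arm_b / L) c(0L, arm_b) else c(arm_b, L)
    lens <- sample(cfg$frag_length[1]:cfg$frag_length[2], S, replace = TRUE)
    margin <- max(lens) + 1L
    starts <- integer(S)
    anchor <- floor(runif(1, arm[1], arm[2] - margin))
    dna_idx <- which(!is_rna)
    if (n_dna > 0) {
      starts[dna_idx[1]] <- anchor
      if (n_dna > 1) {
        for (j in dna_idx[-1]) {
          ok <- FALSE
          for (try in 1:100) {
            d <- round(rpower_law(1, cfg$distance_alpha, cfg$d_min, cfg$d_max))
            p <- anchor + sample(c(-1L, 1L), 1L) * d
            if (p >= arm[1] && p < arm[2] - margin) { starts[j] <- p; ok <- TRUE; break }
          }
          if (!ok) starts[j] <- anchor
        }
      }
    }
    gene_id <- rep(NA_character_, S); strand <- rep("+", S)
    rna_idx <- which(is_rna)
    if (length(rna_idx) > 0) {
      gpool <- genes_by_chrom[[chrom]]
      for (k in seq_along(rna_idx)) {
        j <- rna_idx[k]
        if (complexes$is_xist[i] && k == 1L) {
          g <- gpool[gpool$xist_like, ][1, ]
        } else {
          # XIST-like genes are transcribed only via the attachment process
          bg <- gpool[!gpool$xist_like, , drop = FALSE]
          if (nrow(bg) == 0) bg <- gpool
          g <- bg[sample(nrow(bg), 1L), ]
        }
        gene_id[j] <- g$gene_id; strand[j] <- g$strand
        glen <- g$end - g$start + 1L
        lens[j] <- min(lens[j], glen)
        starts[j] <- g$start - 1L + sample.int(glen - lens[j] + 1L, 1L) - 1L
      }
    }
    mol_l[[i]] <- tibble(
      complex_id = complexes$complex_id[i], modality = if_else(is_rna, "RNA", "DNA"),
      chrom = chrom, start = as.integer(starts), length = lens,
      strand = strand,
      gene_id = gene_id,
      is_xist = !is.na(gene_id) & gene_id %in% ref$gene_sets$xist)
  }
  molecules <- dplyr::bind_rows(mol_l)
  molecules$molecule_id <- sprintf("M%07d", seq_len(nrow(molecules)))
  molecules <- molecules |>
    dplyr::left_join(dplyr::select(complexes, "complex_id", "cell_id",
                                   "gem", "i7"), by = "complex_id") |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "cb1", "cb2", "cb3"),
                     by = "cell_id")
  molecules$gem_umi <- random_seqs(nrow(molecules), 12L)
  molecules$linker_umi <- random_seqs(nrow(molecules), 5L)

  # PCR duplication: Poisson(duplicate_rate) extra copies per molecule
  n_extra <- if (cfg$duplicate_rate > 0) rpois(nrow(molecules), cfg$duplicate_rate) else integer(nrow(molecules))
  occ <- rep(seq_len(nrow(molecules)), 1L + n_extra)
  reads <- molecules[occ, ]
  reads$is_duplicate <- duplicated(occ)
  reads$duplicate_of <- if_else(reads$is_duplicate, reads$molecule_id, NA_character_)
  reads$read_id <- sprintf("R%08d", seq_len(nrow(reads)))
  reads <- reads[sample(nrow(reads)), ]  # shuffle so input order carries no signal

  structure(list(cells = cells, complexes = complexes, molecules = molecules,
                 reads = reads, tables = tables, ref = ref, config = cfg,
                 seed = seed),
            class = "music_ground_truth")
}

random_seqs <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Noise configuration for read emission
#'
#' @param substitution_rate Per-base substitution probability on all reads.
#' @param barcode_mismatch_rate Per-read probability of one substitution in a
#'   randomly chosen barcode segment.
#' @param ag_tail_rate Probability of appending a >20-bp A or G homopolymer to
#'   a DNA insert (poly(dA)-tailing artifact).
#' @param readthrough_rate Probability of appending the RNA linker ssDNA
#'   signature plus downstream bases after an RNA insert (linker read-through).
#' @param low_qual_tail_rate Probability of a low-quality (Q2) 3' tail.
#' @return A `noise_config` list.
#' @export
noise_config <- function(substitution_rate = 0, barcode_mismatch_rate = 0,
                         ag_tail_rate = 0, readthrough_rate = 0,
                         low_qual_tail_rate = 0) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) < 0 | unlist(cfg) > 1)) {
    stop("configuration error: noise rates must lie in [0, 1]")
  }
  structure(cfg, class = "noise_config")
}

.substitute_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Emit MUSIC-layout FASTQ reads from ground truth
#'
#' Renders one (R1, I1, R2) triple per molecule occurrence: R1 = GEM barcode +
#' GEM UMI, I1 = I7 index, R2 = cb3 / spacer / cb2 / spacer / cb1 / linker /
#' insert, truncated to the configured R2 length. Base qualities are constant
#' Q30 except for injected low-quality tails. Molecules whose insert would be
#' shorter than 1 bp after the layout budget are skipped and counted.
#'
#' @param gt A [simulate_ground_truth()] object.
#' @param layout A [music_layout()].
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param dir Output directory for `R1.fastq.gz`, `I1.fastq.gz`,
#'   `R2.fastq.gz` and `truth.tsv`; `NULL` returns records in memory only.
#' @return Invisibly, a list with `truth` (read name -> cell, complex,
#'   modality, locus), `records` (tibble of read sequences) and `n_skipped`.
#' @export
emit_reads <- function(gt, layout = music_layout(), noise = noise_config(),
                       seed = 1L, dir = NULL) {
  stopifnot(inherits(gt, "music_ground_truth"))
  withr_seed(seed + 2L)
  tabs <- gt$tables
  reads <- gt$reads
  chrom_seq <- as.character(gt$ref$seqs)

  budget <- layout$r2_length - layout$linker_offset -
    if_else(reads$modality == "RNA", layout$rna_linker_len, layout$dna_linker_len)
  keep <- budget >= 1L
  n_skipped <- sum(!keep)
  reads <- reads[keep, ]
  budget <- budget[keep]

  ins_len <- pmin(reads$length, budget)
  insert <- substr(chrom_seq[reads$chrom], reads$start + 1L,
                   reads$start + ins_len)
  rc <- reads$strand == "-"
  if (any(rc)) insert[rc] <- rev_comp(insert[rc])

  # artifacts
  n <- nrow(reads)
  if (noise$ag_tail_rate > 0) {
    hit <- reads$modality == "DNA" & runif(n) < noise$ag_tail_rate
    tail_len <- sample(21:40, sum(hit), replace = TRUE)
    insert[hit] <- paste0(insert[hit],
                          strrep(sample(c("A", "G"), sum(hit), replace = TRUE),
                                 tail_len))
  }
  if (noise$readthrough_rate > 0) {
    hit <- reads$modality == "RNA" & runif(n) < noise$readthrough_rate
    insert[hit] <- paste0(insert[hit], layout$shared_prefix, layout$rna_sig1,
                          random_seqs(sum(hit), 12L))
  }

  linker <- if_else(
    reads$modality == "RNA",
    paste0(layout$shared_prefix, layout$rna_sig1, reads$linker_umi, layout$rna_sig2),
    paste0(layout$shared_prefix, reads$linker_umi, layout$dna_sig))
  cb1s <- tabs$cb1[reads$cb1]; cb2s <- tabs$cb2[reads$cb2]; cb3s <- tabs$cb3[reads$cb3]
  if (noise$barcode_mismatch_rate > 0) {
    hit <- which(runif(n) < noise$barcode_mismatch_rate)
    which_bc <- sample(3L, length(hit), replace = TRUE)
    for (k in seq_along(hit)) {
      i <- hit[k]
      tgt <- switch(which_bc[k], cb1s[i], cb2s[i], cb3s[i])
      p <- sample(nchar(tgt), 1L)
      substr(tgt, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(tgt, p, p)), 1L)
      if (which_bc[k] == 1L) cb1s[i] <- tgt
      else if (which_bc[k] == 2L) cb2s[i] <- tgt
      else cb3s[i] <- tgt
    }
  }
  r2 <- paste0(cb3s, layout$spacer1, cb2s, layout$spacer2, cb1s, linker, insert)
  r2 <- substr(r2, 1L, layout$r2_length)
  r1 <- paste0(tabs$gem[reads$gem], reads$gem_umi)
  i1 <- tabs$i7[reads$i7]

  r1 <- .substitute_bases(r1, noise$substitution_rate)
  i1 <- .substitute_bases(i1, noise$substitution_rate)
  r2 <- .substitute_bases(r2, noise$substitution_rate)

  q2 <- strrep("?", nchar(r2))  # Q30
  if (noise$low_qual_tail_rate > 0) {
    hit <- which(runif(n) < noise$low_qual_tail_rate)
    tl <- sample(5:15, length(hit), replace = TRUE)
    tl <- pmin(tl, nchar(r2[hit]) - 1L)
    q2[hit] <- paste0(strrep("?", nchar(r2[hit]) - tl), strrep("#", tl))
  }

  records <- tibble(read_id = reads$read_id, r1 = r1, i1 = i1, r2 = r2,
                    q2 = q2)
  truth <- dplyr::select(reads, "read_id", "cell_id", "complex_id",
                         "molecule_id", "modality", "chrom", "start",
                         "strand", "gene_id", "is_xist", "is_duplicate",
                         "duplicate_of", "cb1", "cb2", "cb3", "gem", "i7",
                         "gem_umi", "linker_umi")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(records$read_id, r1, strrep("?", nchar(r1)),
                file.path(dir, "R1.fastq.gz"))
    write_fastq(records$read_id, i1, strrep("?", nchar(i1)),
                file.path(dir, "I1.fastq.gz"))
    write_fastq(records$read_id, r2, q2, file.path(dir, "R2.fastq.gz"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(truth = truth, records = records, n_skipped = n_skipped))
}

#' Reverse complement of character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

write_fastq <- function(ids, seqs, quals, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  tibble(read_id = sub(" .*", "", names(dss)),
         seq = unname(as.character(dss)),
         qual = unname(as.character(S4Vectors::mcols(dss)$qualities)))
}
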