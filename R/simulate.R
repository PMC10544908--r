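# Primer set used by the amplicon design the simulator emulates.
ITS_PRIMERS <- list(
  ITS1 = list(fwd = "AAGGATCATTGTCGTGACG",    # ITS_PoaF, 18S/ITS1 border
              rev = "GCCGAGAGTCGTGTGGTTTA"),  # Pan5.8S-239R, ITS1/5.8S border
  ITS2 = list(fwd = "ACCATCGAGTCTTTGAACGCA",  # Pan5.8S-316F, within 5.8S
              rev = "AAAGGGTCCATTGAGGCCAT")   # ITS2_582R
)

random_dna <- function(len, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute `k` distinct positions of `seq` to a different base each.
substitute_positions <- function(seq, k) {
  if (k == 0) return(seq)
  len <- nchar(seq)
  pos <- sample.int(len, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a parental sequence pair at an exact divergence
#'
#' The first sequence is uniform random; the second carries
#' `round(length * target_divergence)` substitutions at distinct positions,
#' so the realised p-distance is exactly `round(L * d) / L`.
#'
#' @param length Sequence length (nt).
#' @param target_divergence Target p-distance in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `a`, `b`.
#' @export
generate_species_pair <- function(length, target_divergence, seed) {
  if (target_divergence <= 0 || target_divergence >= 1) {
    abort("target_divergence must be in (0, 1)")
  }
  k <- round(length * target_divergence)
  if (k > length) abort("more substitutions than positions")
  withr::with_seed(as.integer(seed), {
    a <- random_dna(length)
    list(a = a, b = substitute_positions(a, k))
  })
}

#' Generate an intra-species ribotype pool
#'
#' The pool holds the consensus itself plus `n_ribotypes - 1` variants, each
#' carrying `round(L * intra_divergence)` substitutions at random positions.
#' Relative abundances follow a geometric series with ratio
#' `abundance_skew`, normalised to sum to 1 (the consensus is the most
#' abundant ribotype, emulating a dominant rDNA repeat with minor variants).
#'
#' @param consensus Consensus sequence of the species.
#' @param n_ribotypes Pool size (>= 1).
#' @param intra_divergence Per-variant p-distance from the consensus.
#' @param abundance_skew Geometric ratio in (0, 1].
#' @param seed Integer seed.
#' @return A tibble: `ribotype`, `seq`, `abundance`.
#' @export
generate_ribotype_pool <- function(consensus, n_ribotypes, intra_divergence,
                                   abundance_skew, seed) {
  k <- round(nchar(consensus) * intra_divergence)
  seqs <- withr::with_seed(as.integer(seed), {
    c(consensus,
      vapply(seq_len(n_ribotypes - 1)[n_ribotypes > 1], function(i) {
        substitute_positions(consensus, k)
      }, character(1)))
  })
  ab <- abundance_skew^(seq_len(n_ribotypes) - 1)
  tibble::tibble(ribotype = seq_len(n_ribotypes), seq = seqs,
                 abundance = ab / sum(ab))
}

#' Build a synthetic-experiment scenario
#'
#' Describes a complete two-region amplicon experiment: parental species
#' and their between-species divergences, intra-species ribotype pools,
#' the samples (genotype x template) with true species mixing fractions,
#' and the read model (read length, per-base error rate, chimera and
#' contaminant fractions, 12-nt dual barcodes, the published primer set).
#'
#' @param samples Tibble with columns `genotype`, `cross`, `generation`,
#'   `template` and a list-column `mix` of named species fractions
#'   (summing to 1).
#' @param species Species labels; the first is the base from which the
#'   others are derived at their target divergence.
#' @param divergence Named list per region of named numeric vectors:
#'   target p-distance of each non-base species from the base.
#' @param insert_len Named integer vector per region. The ITS2 insert
#'   includes the 51 nt of 5.8S covered by the amplicon.
#' @param n_ribotypes,intra_divergence,abundance_skew Ribotype-pool shape.
#' @param n_reads Read pairs per sample and region.
#' @param error_rate Per-base substitution error rate per mate.
#' @param chimera_frac,contaminant_frac Per-read probabilities.
#' @param read_len Mate length (2 x 300 bp design).
#' @param seed Master seed; everything else derives from it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(samples,
                            species = c("Fp", "Lm"),
                            divergence = list(ITS1 = c(Lm = 0.017),
                                              ITS2 = c(Lm = 0.033)),
                            insert_len = c(ITS1 = 220L, ITS2 = 270L),
                            n_ribotypes = 5, intra_divergence = 0.005,
                            abundance_skew = 0.5,
                            n_reads = 5000, error_rate = 0.003,
                            chimera_frac = 0.01, contaminant_frac = 0.01,
                            read_len = 300L, seed = 1L) {
  check_df_cols(samples, c("genotype", "cross", "generation", "template",
                           "mix"), "samples")
  for (m in samples$mix) {
    if (abs(sum(m) - 1) > 1e-8) abort("sample mixing fractions must sum to 1")
    if (!all(names(m) %in% species)) abort("mix names must be species labels")
  }
  for (rg in names(divergence)) {
    d <- divergence[[rg]]
    if (any(d <= 0 | d > 0.15)) abort("divergences must be in (0, 0.15]")
    if (any(intra_divergence >= min(d))) {
      warn("intra-pool divergence is not below the between-species divergence")
    }
  }
  rates <- c(error_rate, chimera_frac, contaminant_frac)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  structure(list(samples = tibble::as_tibble(samples), species = species,
                 divergence = divergence, insert_len = insert_len,
                 regions = names(divergence),
                 n_ribotypes = n_ribotypes,
                 intra_divergence = intra_divergence,
                 abundance_skew = abundance_skew,
                 n_reads = n_reads, error_rate = error_rate,
                 chimera_frac = chimera_frac,
                 contaminant_frac = contaminant_frac,
                 read_len = as.integer(read_len), barcode_len = 12L,
                 primers = ITS_PRIMERS[names(divergence)],
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' The default study-like scenario
#'
#' One Festuca x Lolium cross followed over generations, both templates,
#' both ITS regions, at the published divergences (ITS1 0.017, ITS2 0.033).
#' True Lolium-type genomic fractions rise from 0.627 (F1) through 0.675
#' (F2) and 0.70 (F3) to 0.96 (BC1 toward Lolium); the cDNA fraction is
#' 0.997 in every hybrid generation (near-total nucleolar dominance by the
#' Lolium parent). Parents are pure samples of their own species.
#'
#' @param generations Which hybrid generations to include.
#' @param genotypes_per_generation Biological replicates per generation.
#' @param include_parents Add one pure parental genotype per species.
#' @param n_reads Read pairs per sample and region.
#' @param seed Master seed.
#' @param ... Passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_scenario <- function(generations = c("F1", "F2", "F3", "BC1"),
                             genotypes_per_generation = 3,
                             include_parents = TRUE,
                             n_reads = 5000, seed = 1L, ...) {
  dna_lolium <- c(F1 = 0.627, F2 = 0.675, F3 = 0.70, BC1 = 0.96)
  generations <- match.arg(generations, names(dna_lolium), several.ok = TRUE)
  rows <- purrr::map_dfr(generations, function(gen) {
    purrr::map_dfr(seq_len(genotypes_per_generation), function(i) {
      f <- dna_lolium[[gen]]
      tibble::tibble(
        genotype = sprintf("%s_g%d", gen, i), cross = "Fp4x_x_Lm",
        generation = gen, template = c("DNA", "cDNA"),
        mix = list(c(Fp = 1 - f, Lm = f), c(Fp = 1 - 0.997, Lm = 0.997)))
    })
  })
  if (include_parents) {
    rows <- bind_rows(rows, purrr::map_dfr(c("Fp", "Lm"), function(sp) {
      mix <- setNames(as.numeric(c("Fp", "Lm") == sp), c("Fp", "Lm"))
      tibble::tibble(genotype = paste0("P_", sp), cross = "Fp4x_x_Lm",
                     generation = paste0("P_", sp),
                     template = c("DNA", "cDNA"), mix = list(mix, mix))
    }))
  }
  scenario_config(samples = rows, n_reads = n_reads, seed = seed, ...)
}

# Deterministically build references, pools, barcodes and the sample sheet
# for a scenario. Returns list(db, pools, sheet).
scenario_assets <- function(scenario) {
  sc <- scenario
  seeds <- derive_seeds(sc$seed, 3L)
  base <- sc$species[1]

  refs <- purrr::map_dfr(seq_along(sc$regions), function(ri) {
    rg <- sc$regions[ri]
    L <- sc$insert_len[[rg]]
    withr::with_seed(seeds[1] + ri, {
      consensus <- setNames(character(length(sc$species)), sc$species)
      consensus[base] <- random_dna(L)
      for (sp in names(sc$divergence[[rg]])) {
        consensus[sp] <- substitute_positions(
          consensus[base], round(L * sc$divergence[[rg]][[sp]]))
      }
      tibble::tibble(id = sprintf("%s_%s_ref", names(consensus), rg),
                     species = names(consensus), region = rg,
                     seq_aligned = unname(consensus))
    })
  })
  db <- ref_db(refs)

  pools <- purrr::map(setNames(sc$regions, sc$regions), function(rg) {
    cons <- db$seq_ungapped[db$region == rg]
    names(cons) <- db$species[db$region == rg]
    purrr::imap(cons, function(s, sp) {
      generate_ribotype_pool(s, sc$n_ribotypes, sc$intra_divergence,
                             sc$abundance_skew,
                             seed = seeds[2] + match(rg, sc$regions) * 100L +
                               match(sp, sc$species))
    })
  })

  n_units <- nrow(sc$samples)
  n_bc <- 2L * n_units * length(sc$regions)
  barcodes <- withr::with_seed(seeds[3], {
    bc <- unique(random_dna(sc$barcode_len, n_bc * 3L))
    bc[seq_len(n_bc)]
  })
  sheet <- purrr::map_dfr(seq_along(sc$regions), function(ri) {
    rg <- sc$regions[ri]
    off <- (ri - 1L) * 2L * n_units
    sc$samples |>
      mutate(sample_id = paste(.data$genotype, .data$template, rg, sep = "_"),
             region = rg,
             fwd_barcode = barcodes[off + 2L * (row_number() - 1L) + 1L],
             rev_barcode = barcodes[off + 2L * (row_number() - 1L) + 2L],
             fwd_primer = sc$primers[[rg]]$fwd,
             rev_primer = sc$primers[[rg]]$rev) |>
      select("sample_id", "genotype", "cross", "generation", "template",
             "region", "fwd_barcode", "rev_barcode", "fwd_primer",
             "rev_primer", "mix")
  })
  list(db = db, pools = pools, sheet = sheet)
}

# Inject iid substitution errors; returns list(seq, qual, n_err).
# Correct bases get Q40 ('I'), injected errors Q10 ('+').
inject_errors <- function(seqs, rate) {
  len <- nchar(seqs)
  qual <- strrep("I", len)
  n_err <- rbinom(length(seqs), len, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      base <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, base), 1)
      substr(qual[i], p, p) <- "+"
    }
  }
  list(seq = seqs, qual = qual, n_err = n_err)
}

#' Simulate the reads of one sample
#'
#' For each read pair: the source class is drawn (contaminant with
#' probability `contaminant_frac`, else chimera with `chimera_frac`, else a
#' normal read), the species by the sample's mixing fractions and the
#' ribotype by pool abundance; chimeras splice ribotypes of two species at
#' a uniform breakpoint; contaminants are unrelated random sequences. The
#' amplicon is assembled as barcode + primer + insert + revcomp(primer) +
#' barcode, split into two (up to) `read_len`-nt mates, and iid
#' substitution errors are injected with qualities consistent with the
#' error model (Q40 correct, Q10 at injected errors).
#'
#' @param scenario A `scenario_config`.
#' @param sample One row of the sample sheet built by [scenario_assets()]
#'   (needs `sample_id`, `region`, `fwd_barcode`, `rev_barcode`, `mix`).
#' @param pools Ribotype pools for the sample's region (list per species).
#' @param seed Integer seed for this sample.
#' @return A list: `pairs` (tibble `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`) and `manifest` (one truth row per read).
#' @export
simulate_sample_reads <- function(scenario, sample, pools, seed) {
  sc <- scenario
  rg <- sample$region
  L <- sc$insert_len[[rg]]
  mix <- sample$mix[[1]]
  if (abs(sum(mix) - 1) > 1e-8) abort("mixing fractions must sum to 1")
  n <- sc$n_reads

  withr::with_seed(as.integer(seed), {
    u <- runif(n)
    is_contam <- u < sc$contaminant_frac
    is_chim <- !is_contam & u < sc$contaminant_frac + sc$chimera_frac

    species <- rep(NA_character_, n)
    ribotype <- rep(NA_character_, n)
    insert <- character(n)

    idx_norm <- which(!is_contam & !is_chim)
    if (length(idx_norm) > 0) {
      sp <- sample(names(mix), length(idx_norm), replace = TRUE, prob = mix)
      species[idx_norm] <- sp
      for (s in unique(sp)) {
        rows <- idx_norm[sp == s]
        ri <- sample.int(nrow(pools[[s]]), length(rows), replace = TRUE,
                         prob = pools[[s]]$abundance)
        ribotype[rows] <- paste0(s, ".", ri)
        insert[rows] <- pools[[s]]$seq[ri]
      }
    }
    for (i in which(is_chim)) {
      present <- names(mix)[mix > 0]
      pair <- if (length(present) >= 2) {
        sample(present, 2, prob = mix[present])
      } else {
        rep(present, 2)
      }
      ra <- sample.int(nrow(pools[[pair[1]]]), 1,
                       prob = pools[[pair[1]]]$abundance)
      rb <- sample.int(nrow(pools[[pair[2]]]), 1,
                       prob = pools[[pair[2]]]$abundance)
      b <- sample.int(L - 1L, 1)
      insert[i] <- paste0(substr(pools[[pair[1]]]$seq[ra], 1, b),
                          substr(pools[[pair[2]]]$seq[rb], b + 1, L))
      species[i] <- paste(pair, collapse = "+")
      ribotype[i] <- paste0(pair[1], ".", ra, "+", pair[2], ".", rb)
    }
    idx_cont <- which(is_contam)
    if (length(idx_cont) > 0) insert[idx_cont] <- random_dna(L, length(idx_cont))

    amp <- paste0(sample$fwd_barcode, sc$primers[[rg]]$fwd, insert,
                  revcomp(sc$primers[[rg]]$rev), revcomp(sample$rev_barcode))
    alen <- nchar(amp)
    rl <- pmin(sc$read_len, alen)
    r1 <- substr(amp, 1, rl)
    r2 <- revcomp(substring(amp, alen - rl + 1L, alen))
    e1 <- inject_errors(r1, sc$error_rate)
    e2 <- inject_errors(r2, sc$error_rate)

    ids <- sprintf("%s_read%05d", sample$sample_id, seq_len(n))
    list(
      pairs = tibble::tibble(id = ids, r1_seq = e1$seq, r1_qual = e1$qual,
                             r2_seq = e2$seq, r2_qual = e2$qual),
      manifest = tibble::tibble(
        read_id = ids, sample_id = sample$sample_id, region = rg,
        species = species, ribotype = ribotype,
        is_chimera = is_chim, is_contaminant = is_contam,
        n_errors_injected = e1$n_err + e2$n_err,
        true_insert = insert))
  })
}

#' Simulate a whole experiment in memory
#'
#' Builds the scenario's references, ribotype pools, barcoded sample sheet,
#' and the reads plus truth manifest for every sample and region.
#'
#' @param scenario A `scenario_config`.
#' @return A list: `db` (a [ref_db()]), `pools`, `sheet` (sample sheet with
#'   `mix` list-column), `pairs` (named list per region of read-pair
#'   tibbles), `manifest` (one tibble over all reads).
#' @export
simulate_experiment <- function(scenario) {
  assets <- scenario_assets(scenario)
  seeds <- derive_seeds(scenario$seed + 1L, nrow(assets$sheet))
  sims <- purrr::map(seq_len(nrow(assets$sheet)), function(i) {
    simulate_sample_reads(scenario, assets$sheet[i, ],
                          assets$pools[[assets$sheet$region[i]]], seeds[i])
  })
  pairs <- purrr::map(setNames(scenario$regions, scenario$regions),
                      function(rg) {
    bind_rows(purrr::map(sims[assets$sheet$region == rg], "pairs"))
  })
  manifest <- bind_rows(purrr::map(sims, "manifest"))
  list(db = assets$db, pools = assets$pools, sheet = assets$sheet,
       pairs = pairs, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' Writes the reference FASTA and metadata, the sample sheet, paired FASTQ
#' per region, the truth manifest, and a scenario JSON, so the pipeline can
#' be run from files exactly as with real data.
#'
#' @param scenario A `scenario_config`.
#' @param dir Target directory.
#' @param overwrite Overwrite an existing directory (default FALSE).
#' @return `dir`, invisibly; files as side effect.
#' @export
generate_dataset <- function(scenario, dir, overwrite = FALSE) {
  if (dir.exists(dir)) {
    if (!overwrite) abort(sprintf("directory '%s' exists (set overwrite)", dir))
  } else {
    dir.create(dir, recursive = TRUE)
  }
  sim <- simulate_experiment(scenario)
  write_fasta(tibble::tibble(id = sim$db$id, seq = sim$db$seq_aligned),
              file.path(dir, "references.fasta"))
  readr::write_tsv(sim$db[, c("id", "species", "region")],
                   file.path(dir, "references_metadata.tsv"))
  sheet_out <- sim$sheet |>
    mutate(mix = vapply(.data$mix, function(m) {
      paste(sprintf("%s=%g", names(m), m), collapse = ";")
    }, character(1)))
  readr::write_tsv(sheet_out, file.path(dir, "sample_sheet.tsv"))
  for (rg in names(sim$pairs)) {
    p <- sim$pairs[[rg]]
    write_fastq(tibble::tibble(id = p$id, seq = p$r1_seq, qual = p$r1_qual),
                file.path(dir, sprintf("%s_R1.fastq", rg)))
    write_fastq(tibble::tibble(id = p$id, seq = p$r2_seq, qual = p$r2_qual),
                file.path(dir, sprintf("%s_R2.fastq", rg)))
  }
  readr::write_tsv(sim$manifest, file.path(dir, "truth_manifest.tsv"))
  cfg <- scenario[setdiff(names(scenario), c("samples", "primers"))]
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
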