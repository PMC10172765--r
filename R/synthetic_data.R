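#' Construct a subtelomeric enrichment profile
#'
#' A piecewise-constant read-density profile anchored at the distal
#' chromosome end: within `distances[k]` (but beyond `distances[k-1]`) of
#' the end, density is `multipliers[k]` times the background; beyond the
#' largest distance it is the background. This encodes the structure the
#' analysis assumes — enrichment localized near chromosome ends, decaying
#' as the analysed region grows.
#'
#' @param distances strictly increasing distances from the end, bp; empty
#'   for a flat (uniform) profile.
#' @param multipliers density multipliers, one per distance band, all > 0.
#' @param background background density in reads/bp (relative weight
#'   across genotypes; within one sample only the shape matters).
#' @return an `enrichment_profile` list.
#' @export
enrichment_profile <- function(distances = numeric(), multipliers = numeric(),
                               background = 1) {
  stopifnot(length(distances) == length(multipliers), background > 0)
  if (length(distances) &&
      (any(distances <= 0) || is.unsorted(distances, strictly = TRUE)))
    subtelo_error("subtelo_config_error",
                  "profile distances must be positive and strictly increasing")
  if (any(multipliers <= 0))
    subtelo_error("subtelo_config_error", "multipliers must be positive")
  structure(list(distances = as.numeric(distances),
                 multipliers = as.numeric(multipliers),
                 background = background),
            class = "enrichment_profile")
}

## Integral of the profile (in background units) over the terminal `span`
## bp of a chromosome of effective length L. Segment k covers
## (L - d_k, L - d_{k-1}]; mass = multiplier * overlap with the window.
profile_mass_in_tail <- function(profile, L, span) {
  span <- min(span, L)
  d <- pmin(profile$distances, L)
  bounds <- c(0, d)                      # distances from the end
  m <- profile$multipliers
  mass <- 0
  for (k in seq_along(m)) {
    seg <- max(0, min(span, bounds[k + 1]) - bounds[k])
    mass <- mass + m[k] * seg
  }
  mass + max(0, span - max(bounds))      # background beyond the last band
}

## Total profile mass over a chromosome of effective length L.
profile_mass_total <- function(profile, L) profile_mass_in_tail(profile, L, L)

#' Closed-form expected normalized density per window under a profile
#'
#' For a window of distance class d on a chromosome of effective length L,
#' the expected per-bp density is proportional to the profile mass in the
#' terminal d bp divided by d, and the genome-average density to the total
#' mass divided by L; their ratio is the expected normalized density. For
#' a single 3x band of width s on a chromosome of length L and d = s this
#' is `3 / (1 + 2 s / L)`, slightly below 3 because the genome average
#' includes the enriched tail.
#'
#' @param profile an [enrichment_profile()].
#' @param chroms effective-chromosome table.
#' @param distances window distance classes, bp.
#' @return data.frame `chrom`, `distance_class`,
#'   `expected_normalized_density`.
#' @export
expected_normalized_density <- function(profile, chroms, distances) {
  out <- expand.grid(chrom = chroms$name, distance_class = distances,
                     stringsAsFactors = FALSE)
  out$expected_normalized_density <- vapply(seq_len(nrow(out)), function(i) {
    L <- chroms$effective_length[match(out$chrom[i], chroms$name)]
    d <- min(out$distance_class[i], L)
    (profile_mass_in_tail(profile, L, d) / d) /
      (profile_mass_total(profile, L) / L)
  }, 0)
  out
}

#' Simulate a genome (chrom.sizes and optional telomere annotation)
#'
#' Desk-scale defaults emulate the mouse karyotype at reduced size: 19
#' autosome-like chromosomes of 0.6-2 Mb. A telomere trim, when given,
#' annotates the terminal `telomere_trim` bp of every chromosome as
#' telomeric repeat, so the effective end sits that far inside the raw
#' end.
#'
#' @param n_chrom number of chromosomes.
#' @param length_range min and max chromosome length, bp.
#' @param telomere_trim bp of terminal telomeric repeat to annotate;
#'   `NULL` for no annotation.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return list with `chrom_sizes` (data.frame `name`, `length`),
#'   `telomere` (BED-style data.frame or `NULL`) and `chroms` (the
#'   effective-chromosome table after applying the annotation).
#' @export
simulate_genome <- function(n_chrom = 19, length_range = c(6e5, 2e6),
                            telomere_trim = NULL, seed = 1) {
  stopifnot(n_chrom >= 1)
  lens <- with_seed(child_seed(seed, "genome"), {
    sort(round(stats::runif(n_chrom, length_range[1], length_range[2])),
         decreasing = TRUE)
  })
  cs <- data.frame(name = paste0("chr", seq_len(n_chrom)), length = lens,
                   stringsAsFactors = FALSE)
  tel <- NULL
  chroms <- data.frame(name = cs$name, raw_length = cs$length,
                       effective_end = cs$length, effective_length = cs$length,
                       stringsAsFactors = FALSE)
  if (!is.null(telomere_trim)) {
    tel <- data.frame(chrom = cs$name, start = cs$length - telomere_trim,
                      end = cs$length, name = "telomere",
                      stringsAsFactors = FALSE)
    chroms <- apply_telomere_annotation(chroms, tel)
  }
  if (!is.null(telomere_trim) && any(chroms$effective_length < 5e3))
    subtelo_warn("chromosome(s) shorter than the smallest default window")
  list(chrom_sizes = cs, telomere = tel, chroms = chroms)
}

#' Simulate aligned reads under an enrichment profile
#'
#' Read start positions are drawn from the piecewise-constant density the
#' profile implies over each chromosome's effective region (inverse-CDF
#' sampling over the segments); chromosomes receive reads in proportion to
#' their total profile mass. Reads extend `read_length` bp and are clipped
#' to the raw chromosome end. The returned manifest records the exact
#' closed-form expected normalized density of every window.
#'
#' @param genome list from [simulate_genome()] (or any list with a
#'   `chroms` effective-chromosome table).
#' @param profile an [enrichment_profile()].
#' @param n_reads total reads to draw.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @param distances distance classes recorded in the manifest.
#' @return list with `reads` (BED-style data.frame, position-sorted) and
#'   `manifest` (profile, parameters, expected normalized densities).
#' @export
simulate_reads <- function(genome, profile, n_reads = 1e5, read_length = 50,
                           seed = 1, distances = c(5e3, 45e3, 450e3, 4500e3)) {
  stopifnot(n_reads >= 1)
  chroms <- genome$chroms
  if (length(profile$distances) &&
      any(profile$distances > min(chroms$effective_length)))
    subtelo_warn("profile band(s) exceed the shortest chromosome; clipped")
  mass <- vapply(chroms$effective_length, function(L)
    profile_mass_total(profile, L), 0) * profile$background
  reads <- with_seed(child_seed(seed, "reads"), {
    n_per <- as.vector(stats::rmultinom(1, n_reads, mass / sum(mass)))
    parts <- lapply(seq_len(nrow(chroms)), function(i) {
      if (n_per[i] == 0) return(NULL)
      L <- chroms$effective_length[i]
      d <- pmin(profile$distances, L)
      # segments measured from the distal end, then the chromosome body
      lo <- c(0, d); hi <- c(d, L)
      mult <- c(profile$multipliers, 1)
      keep <- hi > lo
      lo <- lo[keep]; hi <- hi[keep]; mult <- mult[keep]
      segmass <- mult * (hi - lo)
      seg <- sample.int(length(segmass), n_per[i], replace = TRUE,
                        prob = segmass)
      off <- stats::runif(n_per[i], lo[seg], hi[seg])  # distance from end
      start <- floor(L - off)
      data.frame(chrom = chroms$name[i], start = start,
                 end = pmin(start + read_length, chroms$raw_length[i]),
                 strand = "*", weight = 1, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  reads <- reads[order(match(reads$chrom, chroms$name), reads$start), ]
  rownames(reads) <- NULL
  list(reads = reads,
       manifest = list(
         profile = unclass(profile), n_reads = n_reads,
         read_length = read_length, seed = seed,
         expected = expected_normalized_density(profile, chroms, distances)))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target Ct is a baseline minus log2 of the sample's true fold (one PCR
#' cycle per doubling), plus Gaussian cycle noise; the reference gene is a
#' constant baseline plus noise. Measurements are generated in technical
#' duplicate by default.
#'
#' @param design data.frame with `sample_id`, `genotype`, `true_fold`
#'   (expression relative to the calibrator sample).
#' @param target,reference target and housekeeping-gene names.
#' @param base_ct named baseline Cts, `c(target=, reference=)`.
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param n_replicates technical replicates per well.
#' @param seed integer seed.
#' @return list with `ct_table` and `manifest` (the design and noise).
#' @export
simulate_qpcr <- function(design, target = "TERRA", reference = "Actb",
                          base_ct = c(target = 28, reference = 18),
                          noise_sd = 0.2, n_replicates = 2, seed = 1) {
  stopifnot(all(c("sample_id", "genotype", "true_fold") %in% names(design)),
            all(design$true_fold > 0))
  ct <- with_seed(child_seed(seed, "qpcr"), {
    do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      rbind(
        data.frame(sample_id = design$sample_id[i],
                   genotype = design$genotype[i], target = target,
                   replicate = seq_len(n_replicates),
                   ct = base_ct[["target"]] - log2(design$true_fold[i]) +
                     stats::rnorm(n_replicates, 0, noise_sd)),
        data.frame(sample_id = design$sample_id[i],
                   genotype = design$genotype[i], target = reference,
                   replicate = seq_len(n_replicates),
                   ct = base_ct[["reference"]] +
                     stats::rnorm(n_replicates, 0, noise_sd)))
    }))
  })
  rownames(ct) <- NULL
  list(ct_table = ct,
       manifest = list(design = design, target = target,
                       reference = reference, noise_sd = noise_sd,
                       n_replicates = n_replicates, seed = seed))
}

#' Simulate a per-chromosome-end measurement table
#'
#' Each cell carries a Poisson number of end signals; signal areas and
#' base intensities are lognormal, and damaged ends (a Bernoulli fraction)
#' have their total intensity multiplied by a planted factor. Mean
#' intensity is total over area; cell areas are lognormal.
#'
#' @param n_cells number of cells.
#' @param signals_per_cell_lambda Poisson mean signal count per cell.
#' @param damaged_fraction probability an end is damaged.
#' @param damage_intensity_multiplier planted damaged : non-damaged total
#'   intensity ratio.
#' @param intensity_meanlog,intensity_sdlog lognormal parameters of the
#'   undamaged total intensity.
#' @param seed integer seed.
#' @return list with `measurements` (end-measurement table) and
#'   `manifest` recording the planted multiplier.
#' @export
simulate_end_table <- function(n_cells = 50, signals_per_cell_lambda = 41,
                               damaged_fraction = 0.3,
                               damage_intensity_multiplier = 3.5,
                               intensity_meanlog = log(10),
                               intensity_sdlog = 0.4, seed = 1) {
  meas <- with_seed(child_seed(seed, "ends"), {
    counts <- stats::rpois(n_cells, signals_per_cell_lambda)
    cell_area <- stats::rlnorm(n_cells, log(500), 0.2)
    do.call(rbind, lapply(seq_len(n_cells), function(i) {
      k <- counts[i]
      if (k == 0) return(NULL)
      dmg <- stats::runif(k) < damaged_fraction
      tot <- stats::rlnorm(k, intensity_meanlog, intensity_sdlog) *
        ifelse(dmg, damage_intensity_multiplier, 1)
      area <- stats::rlnorm(k, log(5), 0.3)
      data.frame(cell_id = sprintf("cell%03d", i), genotype = "smc1b1a",
                 end_id = sprintf("cell%03d_end%02d", i, seq_len(k)),
                 damaged = as.integer(dmg), modality = "RNA-FISH",
                 total_intensity = tot, area = area,
                 mean_intensity = tot / area, cell_area = cell_area[i],
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(meas) <- NULL
  list(measurements = meas,
       manifest = list(n_cells = n_cells,
                       signals_per_cell_lambda = signals_per_cell_lambda,
                       damaged_fraction = damaged_fraction,
                       damage_intensity_multiplier = damage_intensity_multiplier,
                       seed = seed))
}

#' Simulate a complete multi-genotype study
#'
#' Generates a genome and per-genotype replicate read sets under
#' per-genotype enrichment profiles — the full input of the subtelomeric
#' density pipeline with known ground truth. Defaults emulate the study
#' design: three genotypes (wild type and two cohesin-mutant genotypes),
#' three replicates each, 100,000 reads per sample, on a 19-chromosome
#' desk-scale genome.
#'
#' @param profiles named list of [enrichment_profile()]s, one per
#'   genotype; the first name is taken as the control genotype.
#' @param n_replicates replicates per genotype.
#' @param n_reads reads per sample.
#' @param read_length read length, bp.
#' @param genome optional pre-built genome ([simulate_genome()]); built
#'   with defaults otherwise.
#' @param distances window distance classes.
#' @param seed master seed; fans out deterministically per sample.
#' @return list: `genome`, `samples` (named list of read tables),
#'   `sample_sheet`, `manifest` (per-genotype expected normalized
#'   densities and expected fold changes vs the control genotype).
#' @export
simulate_study <- function(profiles = list(
                             wt = enrichment_profile(),
                             smc1b1a = enrichment_profile(5e3, 3)),
                           n_replicates = 3, n_reads = 1e5, read_length = 50,
                           genome = NULL,
                           distances = c(5e3, 45e3, 450e3, 4500e3),
                           seed = 1) {
  if (is.null(genome)) genome <- simulate_genome(seed = child_seed(seed, "g"))
  samples <- list(); sheet <- NULL
  expected <- list()
  for (g in names(profiles)) {
    expected[[g]] <- expected_normalized_density(profiles[[g]], genome$chroms,
                                                 distances)
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_rep%d", g, r)
      sim <- simulate_reads(genome, profiles[[g]], n_reads = n_reads,
                            read_length = read_length,
                            seed = child_seed(seed, sid),
                            distances = distances)
      samples[[sid]] <- sim$reads
      sheet <- rbind(sheet, data.frame(sample_id = sid, path = NA_character_,
                                       genotype = g, replicate = r,
                                       assay = "atac",
                                       stringsAsFactors = FALSE))
    }
  }
  control <- names(profiles)[1]
  exp_fc <- lapply(setdiff(names(profiles), control), function(g) {
    e <- expected[[g]]
    e$expected_fold_change <- e$expected_normalized_density /
      expected[[control]]$expected_normalized_density
    e$genotype <- g
    e[, c("genotype", "chrom", "distance_class", "expected_fold_change")]
  })
  list(genome = genome, samples = samples, sample_sheet = sheet,
       manifest = list(seed = seed, n_reads = n_reads,
                       n_replicates = n_replicates, control = control,
                       expected_normalized_density = expected,
                       expected_fold_change = do.call(rbind, exp_fc)))
}

#' Write a simulated study to disk
#'
#' Materializes a [simulate_study()] result as the file set the pipeline
#' consumes: `chrom.sizes`, `telomere.bed` (if annotated), one BED per
#' sample, `sample_sheet.tsv` and `manifest.json`.
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- study$genome$chrom_sizes
  writeLines(sprintf("%s\t%d", cs$name, cs$length),
             file.path(dir, "chrom.sizes"))
  if (!is.null(study$genome$telomere)) {
    tel <- study$genome$telomere
    utils::write.table(
      data.frame(tel$chrom,
                 format(tel$start, scientific = FALSE, trim = TRUE),
                 format(tel$end, scientific = FALSE, trim = TRUE), tel$name),
      file.path(dir, "telomere.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  sheet <- study$sample_sheet
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    rd <- study$samples[[sid]]
    utils::write.table(
      data.frame(rd$chrom, format(rd$start, scientific = FALSE, trim = TRUE),
                 format(rd$end, scientific = FALSE, trim = TRUE)),
      file.path(dir, paste0(sid, ".bed")), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    # paths are relative to the sheet so the directory relocates freely
    sheet$path[i] <- paste0(sid, ".bed")
  }
  write_tsv_table(sheet, file.path(dir, "sample_sheet.tsv"))
  manifest <- study$manifest
  manifest$expected_normalized_density <-
    lapply(manifest$expected_normalized_density, as.list)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
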