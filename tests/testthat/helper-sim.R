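# Shared simulated dataset for unit tests: scaled-down libraries (2e4 reads)
# under the default locus plantings, generated once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 101L) {
  sim_config(seed = seed,
             library_sizes = setNames(
               as.integer(round(2e4 * c(1147753, 599279, 289303, 463800) / 2500135)),
               stage_labels()))
}

sim_pipeline_config <- function(dir, out = file.path(dir, "out")) {
  list(genome = file.path(dir, "genome.fa"),
       refs = list(ncRNA = file.path(dir, "refs/ncRNA.fa"),
                   "repeat" = file.path(dir, "refs/repeat.fa"),
                   mRNA = file.path(dir, "refs/mRNA.fa"),
                   known_miRNA = file.path(dir, "refs/known_miRNA.fa")),
       reads = as.list(file.path(dir, paste0("lib_", stage_labels(), ".fastq"))),
       barcodes = as.list(sim_config()$barcodes),
       adapter = sim_config()$adapter,
       out_dir = out)
}

shared_sim <- function() {
  if (is.null(.sim_cache$libs)) {
    dir <- file.path(tempdir(), "mirstage_shared_sim")
    .sim_cache$libs <- simulate_dataset(small_sim_config(), dir)
    .sim_cache$dir <- dir
  }
  list(libs = .sim_cache$libs, dir = .sim_cache$dir)
}

shared_pipeline <- function() {
  if (is.null(.sim_cache$res)) {
    s <- shared_sim()
    .sim_cache$res <- run_pipeline(sim_pipeline_config(s$dir))
  }
  list(res = .sim_cache$res, libs = .sim_cache$libs, dir = .sim_cache$dir)
}
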