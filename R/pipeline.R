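#' Run the testes cluster pipeline on a simulated dataset
#'
#' Convenience wrapper: applies [call_testes_clusters()] to the libraries of
#' a [simulate_dataset()] result using its genome, design and library stats.
#'
#' @param sim output of [simulate_dataset()] (testes design).
#' @param ... passed to [call_testes_clusters()].
#' @return see [call_testes_clusters()].
#' @export
run_testes_pipeline <- function(sim, ...) {
  testes <- sim$config$design$sample_id[sim$config$design$role == "testes"]
  call_testes_clusters(sim$reads_by_sample[testes], sim$genome,
                       sim$config$design, sim$libs, ...)
}

#' Run the oocyte cluster pipeline on a simulated dataset
#'
#' Builds the PIWIL1/PIWIL3 IP window tables (all 18-32-nt reads, fractional
#' counts, RPM against the library's 18-32-nt total) on the configured
#' tiling and applies [call_oocyte_clusters()] with the wild-type oocyte
#' libraries.
#'
#' @param sim output of [simulate_dataset()] (oocyte design).
#' @param ... passed to [call_oocyte_clusters()].
#' @return see [call_oocyte_clusters()].
#' @export
run_oocyte_pipeline <- function(sim, ...) {
  design <- sim$config$design
  windows <- tile_genome(sim$genome, sim$config$window_size)
  ip_table <- function(role) {
    s <- design$sample_id[design$role == role]
    stopifnot(length(s) == 1)
    counts <- fractional_count(sim$reads_by_sample[[s]], windows,
                               size_min = 18, size_max = 32, sample = s)
    to_rpm(counts, sim$libs, denominator = "total_18_32")
  }
  wt_oo <- design$sample_id[design$role == "oocyte" & design$genotype == "WT"]
  call_oocyte_clusters(ip_table("ip_piwil1"), ip_table("ip_piwil3"),
                       sim$reads_by_sample[wt_oo], sim$libs, ...)
}
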