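Package: cardiodti
Title: Motion-Compensated Cardiac Diffusion MRI: Waveform Design, Simulation and Tensor Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale development and validation of motion-compensated
    cardiac diffusion-weighted MRI. Designs diffusion-encoding gradient waveforms
    (classic Stejskal-Tanner and second-order motion-compensated designs with
    nulled zeroth, first and second gradient moments) under hardware amplitude and
    slew-rate limits; forward-simulates diffusion-weighted signals from
    synthetic phantoms (polyvinylpyrrolidone vial series and short-axis cardiac
    annuli with transmural fiber helix structure and injury regions) including
    bulk-motion phase accrual, intravoxel dephasing and Rician noise; fits the
    diffusion tensor from six-direction data, producing apparent diffusion
    coefficient and fractional anisotropy maps with region-of-interest statistics;
    and provides left-ventricular ejection fraction, extracellular volume fraction
    and distribution-aware group-comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
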