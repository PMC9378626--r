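Package: ptychotomo
Title: Electron Ptychographic Tomography: Simulation, Phase Retrieval and
    3D Reconstruction
Version: 0.1.0
Authors@R:
    person("ptychotomo", "developers", email = "ptychotomo@example.org",
           role = c("aut", "cre"))
Description: Tools for defocused-probe electron ptychographic tomography of
    weakly scattering specimens. Simulates 4D-STEM tilt series of voxelized
    phase phantoms (DNA-origami strands, gold nanoparticles, amorphous carbon
    support) with Poisson shot noise at specified electron doses, recovers 2D
    complex object waves by the extended ptychographic iterative engine (ePIE)
    with post-acquisition defocus refinement, aligns tilt series by phase
    correlation, reconstructs 3D volumes with a Fourier iterative (GENFIRE
    style) algorithm, and quantifies results via normalized histogram contrast
    ratios and Fourier ring/shell correlation with the half-bit criterion.
    Includes analytic electron-optical calculators (relativistic wavelength,
    ptychographic transfer band, CTF first zero, probe geometry, dose and
    overlap accounting) and MRC / plain-text / JSON I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
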