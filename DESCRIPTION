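Package: threadsim
Title: Real-Time Inextensible Surgical Thread Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Position-based dynamics simulation of surgical thread as a
    discrete Cosserat rod. Rod elements carry unit quaternion material
    frames; shear-stretch and bend-twist constraints are projected with a
    Gauss-Seidel scheme, and inextensibility is enforced every iteration by
    a direct tridiagonal solve of the chained distance constraints (Thomas
    algorithm). Includes continuous sphere-sphere collision detection with
    spatial hashing, position-level contact and friction constraints,
    time-step-independent velocity damping, scripted validation scenes
    (hanging spiral, compression release, twist winding, knot tying,
    cylinder binding), scene file input and output, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
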