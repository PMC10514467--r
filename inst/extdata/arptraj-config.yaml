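# arptraj shipped configuration.
#
# Everything in this file is data, not code: chain->subunit maps for the
# structure dialects the package knows about, subdomain residue ranges,
# named residue anchors, clamp-twist bead definitions, SASA/contact
# parameters, and steering presets. Users may copy and edit this file and
# pass it via `config=` to override any entry.
#
# Canonical subunit names: Arp2, Arp3, ARPC1..ARPC5, mother filament
# MA0..MA9, daughter filament DA1..DA4.
#
# Subdomain ranges for the deposited dialects are the canonical actin
# subdomain boundaries mapped onto Arp numbering. They are PROVISIONAL
# defaults (the authoritative per-structure boundaries are a property of
# each deposited model) and are meant to be overridden per analysis.
# Deposited-dialect chain letters are likewise provisional and should be
# checked against the coordinate file in hand.

dialects:
  synthetic:
    chains:
      Arp3: "A"
      Arp2: "B"
      ARPC1: "C"
      ARPC2: "D"
      ARPC3: "E"
      ARPC4: "F"
      ARPC5: "G"
      MA0: "H"
      MA1: "I"
      MA2: "J"
      MA3: "K"
      MA4: "L"
      MA5: "M"
      MA6: "N"
      MA7: "O"
      MA8: "P"
      MA9: "Q"
      DA1: "R"
      DA2: "S"
      DA3: "T"
      DA4: "U"
    subdomains:
      Arp2:  {sd1: [[1, 3]], sd2: [[4, 6]], sd3: [[7, 9]], sd4: [[10, 12]]}
      Arp3:  {sd1: [[1, 3]], sd2: [[4, 6]], sd3: [[7, 9]], sd4: [[10, 12]]}
      actin: {sd1: [[1, 3]], sd2: [[4, 6]], sd3: [[7, 9]], sd4: [[10, 12]]}
    anchors:
      arp2_I41:    {subunit: Arp2,  resno: 20}
      arp2_F173:   {subunit: Arp2,  resno: 21}
      arp2_I140:   {subunit: Arp2,  resno: 22}
      arpc3_Y58:   {subunit: ARPC3, resno: 20}
      actinD2_M44: {subunit: DA2,   resno: 20}
    clamp_beads:
      - {subunit: ARPC2, resno: [[1, 1]]}
      - {subunit: ARPC2, resno: [[2, 2]]}
      - {subunit: ARPC4, resno: [[1, 1]]}
      - {subunit: ARPC4, resno: [[2, 2]]}
    mf_excluded: [MA1, MA0, MA5, MA7, MA8]

  "7TPT":
    chains:
      Arp3: "A"
      Arp2: "B"
      ARPC1: "C"
      ARPC2: "D"
      ARPC3: "E"
      ARPC4: "F"
      ARPC5: "G"
      MA0: "H"
      MA1: "I"
      MA2: "J"
      MA3: "K"
      MA4: "L"
      MA5: "M"
      MA6: "N"
      MA7: "O"
      MA8: "P"
      MA9: "Q"
      DA1: "R"
      DA2: "S"
      DA3: "T"
      DA4: "U"
    subdomains: &actin_subdomains
      # canonical actin subdomain boundaries (provisional for the Arps)
      Arp2:
        sd1: [[1, 32], [70, 144], [338, 375]]
        sd2: [[33, 69]]
        sd3: [[145, 180], [270, 337]]
        sd4: [[181, 269]]
      Arp3:
        sd1: [[1, 32], [70, 152], [350, 418]]
        sd2: [[33, 69]]
        sd3: [[153, 188], [282, 349]]
        sd4: [[189, 281]]
      actin:
        sd1: [[1, 32], [70, 144], [338, 375]]
        sd2: [[33, 69]]
        sd3: [[145, 180], [270, 337]]
        sd4: [[181, 269]]
    anchors: &canonical_anchors
      arp2_I41:    {subunit: Arp2,  resno: 41}
      arp2_F173:   {subunit: Arp2,  resno: 173}
      arp2_I140:   {subunit: Arp2,  resno: 140}
      arpc3_Y58:   {subunit: ARPC3, resno: 58}
      actinD2_M44: {subunit: DA2,   resno: 44}
    clamp_beads:
      # four backbone-atom sets on the clamp subunits; provisional choices
      - {subunit: ARPC2, resno: [[54, 60]]}
      - {subunit: ARPC2, resno: [[145, 151]]}
      - {subunit: ARPC4, resno: [[60, 66]]}
      - {subunit: ARPC4, resno: [[150, 156]]}
    mf_excluded: [MA1, MA0, MA5, MA7, MA8]

  "4JD2":
    chains:
      Arp3: "A"
      Arp2: "B"
      ARPC1: "C"
      ARPC2: "D"
      ARPC3: "E"
      ARPC4: "F"
      ARPC5: "G"
      GMF: "H"
    subdomains: *actin_subdomains
    anchors: *canonical_anchors
    clamp_beads:
      - {subunit: ARPC2, resno: [[54, 60]]}
      - {subunit: ARPC2, resno: [[145, 151]]}
      - {subunit: ARPC4, resno: [[60, 66]]}
      - {subunit: ARPC4, resno: [[150, 156]]}
    mf_excluded: []

# Shrake-Rupley SASA parameters
sasa:
  probe_radius: 1.4        # angstrom
  n_sphere_points: 960     # deterministic generalized-spiral point set
  radii:                   # Bondi-style van der Waals radii, angstrom
    "C": 1.70
    "N": 1.55               # quoted: bare N/Y are YAML 1.1 booleans
    "O": 1.52
    "S": 1.80
    "P": 1.80
    "H": 1.20
    "SE": 1.90
    "FE": 1.80
    "MG": 1.73
    "K": 2.75
    "CL": 1.75

# sigmoidal contact-score parameters: w(d) = 1 / (1 + exp((d - d0) / sigma))
contacts:
  d0: 4.0                  # angstrom
  sigma: 0.5               # angstrom
  cutoff: 10.0             # neighbor-list cutoff, angstrom
  threshold: 1.0           # interface-residue mean-score threshold

# order-parameter defaults
geometry:
  smooth_window: 50        # frames (5 ns at a 100 ps frame interval)
  basin_bins: 50
  basin_pad: 0.05

# coarse-grained steering surrogate
steer:
  spring_k: 10000          # restraint spring constant, energy / A^2
  network_k: 50            # elastic-network stiffness, energy / A^2
  cutoff: 60               # network edge cutoff, angstrom
  gamma: 1.0e+6             # friction, energy * step / A^2
  kT: 2.5                  # thermal energy (kJ/mol at ~300 K)
  dt: 1.0                  # integration step (stability: dt < 2*gamma/k_max)
  presets:                 # ramp/hold step counts mirroring the
    pull60:  {ramp: 60000,  hold: 140000}   # 60/100/150 ns pulls each
    pull100: {ramp: 100000, hold: 100000}   # continued unbiased to ~200 ns
    pull150: {ramp: 150000, hold: 50000}
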