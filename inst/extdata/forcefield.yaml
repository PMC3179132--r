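# United-atom force field for the MIP model system.
# sigma in nm as printed (converted to Angstrom on load), epsilon in kJ/mol,
# charge in elementary units, mass in g/mol.
# Geometry is given as internal coordinates (bond Angstrom, angles degrees);
# bends are held at their reference values, bond lengths are fixed, and
# flexibility enters through the listed rotatable bonds (cosine-series
# torsions U = 0.5*c1*(1+cos phi) + 0.5*c2*(1-cos 2 phi) + 0.5*c3*(1+cos 3 phi)).
# Torsion constants are a replaceable parameter set in the TraPPE style.
version: 1
constants:
  coulomb_k: 1389.35457644382   # 1/(4 pi eps0), kJ Angstrom mol^-1 e^-2
  kB: 0.008314462618            # kJ mol^-1 K^-1 (molar Boltzmann constant)
  kB_SI: 1.380649e-23           # J/K
  N_A: 6.02214076e+23
  cutoff_mixture: 14.0          # Angstrom, LJ cutoff for the liquid stage
  cutoff_gcmc: 10.6             # Angstrom, LJ + Coulomb cutoff for adsorption
  dsf_alpha: 0.2                # 1/Angstrom, damped shifted-force damping
species:
  PRZ:
    rigid: true
    atoms:
      - {id: C1, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: C2, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: N3, sigma: 0.345, epsilon: 0.233, charge: -0.66, mass: 14.007}
      - {id: C4, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: C5, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: N6, sigma: 0.345, epsilon: 0.233, charge: -0.66, mass: 14.007}
    check: {charge_sum: 0.0, sigma_sum: 2.186}
    bonds: [[1, 2], [2, 3], [3, 4], [4, 5], [5, 6], [6, 1]]
    geometry: {type: hexagon, bond: 1.40}
    symmetry_number: 4   # D2h pyrazine, proper rotations
    functional:
      nitrogens: [3, 6]
      adjacent_carbons: {"3": [2, 4], "6": [5, 1]}
  PMD:
    rigid: true
    atoms:
      - {id: C1, sigma: 0.390, epsilon: 0.391, charge:  0.66, mass: 13.019}
      - {id: N2, sigma: 0.345, epsilon: 0.233, charge: -0.66, mass: 14.007}
      - {id: C3, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: C4, sigma: 0.370, epsilon: 0.420, charge:  0.00, mass: 13.019}
      - {id: C5, sigma: 0.374, epsilon: 0.399, charge:  0.33, mass: 13.019}
      - {id: N6, sigma: 0.345, epsilon: 0.233, charge: -0.66, mass: 14.007}
    check: {charge_sum: 0.0, sigma_sum: 2.198}
    bonds: [[1, 2], [2, 3], [3, 4], [4, 5], [5, 6], [6, 1]]
    geometry: {type: hexagon, bond: 1.40}
    symmetry_number: 2   # C2v pyrimidine
    functional:
      nitrogens: [2, 6]
      adjacent_carbons: {"2": [1, 3], "6": [5, 1]}
  MAA:
    rigid: false
    atoms:
      - {id: H1, sigma: 0.000, epsilon: 0.000, charge:  0.37, mass:  1.008}
      - {id: O2, sigma: 0.302, epsilon: 0.773, charge: -0.46, mass: 15.999}
      - {id: C3, sigma: 0.390, epsilon: 0.341, charge:  0.42, mass: 12.011}
      - {id: O4, sigma: 0.305, epsilon: 0.657, charge: -0.45, mass: 15.999}
      - {id: C5, sigma: 0.385, epsilon: 0.166, charge:  0.12, mass: 12.011}
      - {id: C6, sigma: 0.368, epsilon: 0.707, charge:  0.00, mass: 14.027}
      - {id: C7, sigma: 0.375, epsilon: 0.815, charge:  0.00, mass: 15.035}
    check: {charge_sum: 0.0, sigma_sum: 2.125}
    bonds: [[1, 2], [2, 3], [3, 4], [3, 5], [5, 6], [5, 7]]
    # NeRF internal coordinates: [atom, bond_ref, length, angle_ref, angle,
    # dihedral_ref, dihedral]; first three atoms seed the frame.
    geometry:
      type: zmat
      zmat:
        - [5]                               # C5 at origin
        - [6, 5, 1.33]                      # C6 =CH2
        - [7, 5, 1.54, 6, 122.0]            # C7 CH3
        - [3, 5, 1.52, 6, 119.0, 7, 180.0]  # C3 carboxyl carbon
        - [4, 3, 1.214, 5, 126.0, 6, 0.0]   # O4 carbonyl oxygen
        - [2, 3, 1.364, 5, 111.0, 4, 180.0] # O2 hydroxyl oxygen
        - [1, 2, 0.970, 3, 107.0, 4, 0.0]   # H1 acid hydrogen, syn to O4
    rotatable:
      - {axis: [5, 3], moving: [4, 2, 1], dihedral: [6, 5, 3, 4],
         c: [0.0, 20.0, 0.0]}               # conjugated C-C(=O) twist
      - {axis: [3, 2], moving: [1], dihedral: [4, 3, 2, 1],
         c: [-25.0, 20.0, 0.0]}             # acid O-H, syn minimum
    functional:
      hydrogen: 1
      carbonyl_oxygen: 4
  EGDMA:
    rigid: false
    atoms:
      - {id: C1,  sigma: 0.368, epsilon: 0.707, charge:  0.00, mass: 14.027}
      - {id: C2,  sigma: 0.385, epsilon: 0.166, charge:  0.12, mass: 12.011}
      - {id: C3,  sigma: 0.375, epsilon: 0.815, charge:  0.00, mass: 15.035}
      - {id: C4,  sigma: 0.390, epsilon: 0.341, charge:  0.42, mass: 12.011}
      - {id: O5,  sigma: 0.305, epsilon: 0.657, charge: -0.45, mass: 15.999}
      - {id: O6,  sigma: 0.302, epsilon: 0.773, charge: -0.46, mass: 15.999}
      - {id: C7,  sigma: 0.395, epsilon: 0.382, charge:  0.37, mass: 14.027}
      - {id: C8,  sigma: 0.395, epsilon: 0.382, charge:  0.37, mass: 14.027}
      - {id: O9,  sigma: 0.302, epsilon: 0.773, charge: -0.46, mass: 15.999}
      - {id: C10, sigma: 0.390, epsilon: 0.341, charge:  0.42, mass: 12.011}
      - {id: C11, sigma: 0.385, epsilon: 0.166, charge:  0.12, mass: 12.011}
      - {id: O12, sigma: 0.305, epsilon: 0.657, charge: -0.45, mass: 15.999}
      - {id: C13, sigma: 0.375, epsilon: 0.815, charge:  0.00, mass: 15.035}
      - {id: C14, sigma: 0.367, epsilon: 0.707, charge:  0.00, mass: 14.027}
    check: {charge_sum: 0.0, sigma_sum: 5.039}
    bonds: [[1, 2], [2, 3], [2, 4], [4, 5], [4, 6], [6, 7], [7, 8], [8, 9],
            [9, 10], [10, 11], [10, 12], [11, 13], [11, 14]]
    geometry:
      type: zmat
      zmat:
        - [2]                                  # C2 at origin
        - [1, 2, 1.33]                         # C1 =CH2
        - [3, 2, 1.54, 1, 122.0]               # C3 CH3
        - [4, 2, 1.52, 1, 119.0, 3, 180.0]     # C4 ester carbonyl carbon
        - [5, 4, 1.20, 2, 126.0, 1, 0.0]       # O5 carbonyl oxygen
        - [6, 4, 1.344, 2, 111.0, 5, 180.0]    # O6 ester oxygen
        - [7, 6, 1.41, 4, 115.0, 5, 0.0]       # C7 OCH2, cis ester
        - [8, 7, 1.54, 6, 109.5, 4, 180.0]     # C8 OCH2
        - [9, 8, 1.41, 7, 109.5, 6, 180.0]     # O9 ester oxygen
        - [10, 9, 1.344, 8, 115.0, 7, 180.0]   # C10 carbonyl carbon
        - [12, 10, 1.20, 9, 121.0, 8, 0.0]     # O12 carbonyl oxygen
        - [11, 10, 1.52, 9, 111.0, 12, 180.0]  # C11 sp2 carbon
        - [13, 11, 1.54, 10, 116.0, 12, 180.0] # C13 CH3
        - [14, 11, 1.33, 10, 122.0, 13, 180.0] # C14 =CH2
    rotatable:
      - {axis: [2, 4],  moving: [5, 6, 7, 8, 9, 10, 11, 12, 13, 14],
         dihedral: [1, 2, 4, 6],  c: [0.0, 20.0, 0.0]}
      - {axis: [4, 6],  moving: [7, 8, 9, 10, 11, 12, 13, 14],
         dihedral: [5, 4, 6, 7],  c: [8.0, 30.0, 0.0]}   # ester planarity
      - {axis: [6, 7],  moving: [8, 9, 10, 11, 12, 13, 14],
         dihedral: [4, 6, 7, 8],  c: [0.0, 0.0, 3.0]}
      - {axis: [7, 8],  moving: [9, 10, 11, 12, 13, 14],
         dihedral: [6, 7, 8, 9],  c: [0.0, 0.0, 5.0]}
      - {axis: [8, 9],  moving: [10, 11, 12, 13, 14],
         dihedral: [7, 8, 9, 10], c: [0.0, 0.0, 3.0]}
      - {axis: [9, 10], moving: [11, 12, 13, 14],
         dihedral: [8, 9, 10, 12], c: [8.0, 30.0, 0.0]}  # ester planarity
      - {axis: [10, 11], moving: [13, 14],
         dihedral: [9, 10, 11, 14], c: [0.0, 20.0, 0.0]}
    functional:
      carbons: [7, 8]
      oxygens: [5, 12]
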