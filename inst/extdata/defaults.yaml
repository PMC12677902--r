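network:
  pools:
    RA: 120
    INT: 50
    X: 50
  n_circuits: 20
  ra_per_circuit:
  - 3
  - 10
  int_per_circuit:
  - 1
  - 4
  x_per_circuit:
  - 1
  - 4
  ra_to_int_in:
  - 3
  - 8
  int_to_ra_out:
  - 2
  - 4
  x_to_int_out:
  - 1
  - 3
  int_to_x_out:
  - 1
  - 2
  g_ranges:
    RA->RA:
    - 23.0
    - 24.5
    RA->INT:
    - 12.0
    - 18.0
    X->INT:
    - 2.0
    - 5.0
    INT->RA:
    - 2.0
    - 5.0
    INT->X:
    - 28.0
    - 45.0
cells:
  RA:
    C_m: 40.0
    g_L: 2.5
    E_L: -80.0
    g_Na: 450.0
    E_Na: 55.0
    g_K: 150.0
    E_K: -90.0
    g_CaL: 20.0
    E_Ca: 120.0
    g_CaT: 0.0
    g_SK: 100.0
    g_A: 5.0
    g_H: 0.0
    E_H: -40.0
    ca_alpha: 0.0004
    ca_tau: 40.0
    ca0: 0.05
  X:
    C_m: 100.0
    g_L: 4.0
    E_L: -88.0
    g_Na: 450.0
    E_Na: 55.0
    g_K: 200.0
    E_K: -90.0
    g_CaL: 5.0
    E_Ca: 120.0
    g_CaT: 70.0
    g_SK: 7.0
    g_A: 0.0
    g_H: 6.0
    E_H: -40.0
    ca_alpha: 0.0001
    ca_tau: 50.0
    ca0: 0.05
  INT:
    C_m: 75.0
    g_L: 4.0
    E_L: -58.0
    g_Na: 700.0
    E_Na: 55.0
    g_K: 800.0
    E_K: -90.0
    g_CaL: 2.0
    E_Ca: 120.0
    g_CaT: 3.0
    g_SK: 0.0
    g_A: 0.0
    g_H: 2.0
    E_H: -20.0
    ca_alpha: 0.0001
    ca_tau: 50.0
    ca0: 0.05
solver:
  method: fixed_rk4_em
  dt: 0.01
  duration: 1000.0
  record_stride: 10
  rel_tol: 1.0e-06
  abs_tol: 1.0e-08
noise:
  sigma_pct: 0.0
  seed: 1
experiment:
  kick_nA: 0.5
  kick_ms: 18.0
  fold_up: 20.0
  n_sims: 100.0
seeds:
  network: 1
  noise: 1
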