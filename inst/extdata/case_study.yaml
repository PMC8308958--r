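press:
  die_diameter: 11.279999999999999
  fill_depth: 10.0
  dosing_height: 7.0
  min_punch_distance: 3.2
  n_stations: 4.0
  turret_rpm: 20.0
  paddle_rpm: 60.0
  n_compartments: 12.0
  fill_ratios:
  - 0.4
  - 0.35
  - 0.25
  pipe_inner_diameter: 45.0
  midstream_diameter: 33.0
  velocity_ratio: 2.0
  pipe_height: 200.0
  compartment_capacity: 2.098588919146227
  machine_compliance: 0.035878633610206
  punch_offset: 0.116394270740074
  sim_duration: 25.0
  use_consolidated_density: yes
materials:
  A150:
    solid_density: 2.842
    bulk_density: 0.68
    tapped_density: 0.75
    consolidated_bulk_density: 0.73
    kawakita:
      rho0: 1.22954
      a: 0.4981
      b: 0.0072
    recovery:
      P_low: 30.0
      P_high: 400.0
      rho_P_max:
      - 1.348887235269536
      - 1.950795265699219
      rho_P_0:
      - 1.345887235269536
      - 1.910795265699219
      rho_out_die:
      - 1.340887235269536
      - 1.905795265699219
      correction_offset: 0.0
    sigma0_pure: 5222.178498095783652
    kb_pure: 18.890000000000001
  A60:
    solid_density: 2.849
    bulk_density: 1.33
    tapped_density: 1.51
    consolidated_bulk_density: 1.41
    kawakita:
      rho0: 1.62302
      a: 0.4891
      b: 0.0041
    recovery:
      P_low: 30.0
      P_high: 400.0
      rho_P_max:
      - 1.714886774659645
      - 2.331372083862023
      rho_P_0:
      - 1.711886774659646
      - 2.291372083862023
      rho_out_die:
      - 1.706886774659646
      - 2.286372083862023
      correction_offset: 0.0
    sigma0_pure: 48.310000000000002
    kb_pure: 15.09
schedule:
- start_min: 0.0
  material: A150
  lot: A150-lot-1
- start_min: 1.0
  material: A60
  lot: A60-lot-1
- start_min: 13.0
  material: A150
  lot: A150-lot-2
strength:
  c1: 19.989999999999998
  c2: 5.56
  c3: 28.32
  m: 3.8
  'n': 15.09
  reference: A150
sampling_times:
- 1.0
- 2.0
- 3.0
- 4.0
- 5.0
- 6.0
- 7.0
- 8.0
- 10.0
- 12.0
- 14.0
- 16.0
- 18.0
- 19.0
- 20.0
- 21.0
- 22.0
- 23.0
- 24.0
- 25.0
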