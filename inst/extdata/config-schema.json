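{
  "description": "Device configuration schema. JSON or YAML; every key optional (defaults come from the named coil's reference configuration, default R2000). Lengths in micrometres, currents in mA, flow in uL/min, diameters in nm; converted to SI on load. Unknown keys are rejected.",
  "sections": {
    "coil": {
      "name": "one of R500 | R1000 | R1500 | R2000 (selects outer radius and turn count)",
      "outer_radius_um": "outer radius of the outermost turn",
      "n_turns": "number of turns (integer)",
      "wire_width_um": "wire width (default 10)",
      "wire_height_um": "wire height (default 10)",
      "spacing_um": "gap between adjacent wires (default 10)",
      "current_mA": "drive current, design range 100-700 (values outside warn)",
      "conductivity_S_m": "wire conductivity (default copper 5.96e7)"
    },
    "channel": {
      "width_um": "channel width (lateral y), design range 50-1000",
      "height_um": "channel height (default 50)",
      "length_um": "channel length along the flow axis",
      "coil_separation_um": "gap between wire top surface and channel floor, design range 5-100",
      "lateral_offset_um": "channel axis offset from the coil center (default 0)"
    },
    "fluid": {
      "density_kg_m3": "default 1000 (sweat)",
      "viscosity_Pa_s": "default 1e-3 (sweat)",
      "flow_rate_uL_min": "default 1",
      "rel_permeability": "default 1",
      "rel_permittivity": "default 80 (sweat)"
    },
    "particle": {
      "diameter_nm": "MNP diameter, design range 10-60",
      "rel_permeability": "default 5000 (magnetite)",
      "rel_permittivity": "default 10 (iron-oxide range 10-40)",
      "mass_density_kg_m3": "default 5200; used only by the inertial cross-check"
    },
    "electrodes": {
      "height_um": "electrode height, design range 20-500 (default 50)",
      "length_um": "detection-zone length (default 500)",
      "conductivity_S_m": "metadata only; capacitance assumes ideal conductors",
      "voltage_V": "drive voltage (default 5, metadata only)"
    },
    "stack": {
      "wall_thickness_um": "PDMS wall between electrode and channel (default 5)",
      "eps_wall": "PDMS relative permittivity (default 2.7)"
    },
    "simulation": {
      "horizon_s": "simulated time horizon (default 60, max 600)",
      "n_particles": "ensemble size (default 500)",
      "seed": "base RNG seed (default 1)",
      "inject_time_s": "continuous-injection window (default 10)",
      "series_terms": "odd Fourier terms of the duct-flow series (default 51)",
      "step_length_um": "target spatial step of the particle integrator (default 1)",
      "dt_max_s": "maximum integrator step (default 0.05)",
      "dt_min_s": "minimum integrator step (default 1e-7)",
      "rel_tol": "integrator relative tolerance (default 1e-6)",
      "quadrature": "wire cross-section sub-filament quadrature (default false)",
      "n_sub": "sub-filament grid order per wire (default 3)",
      "mnp_concentration_m3": "physical MNP number concentration at the inlet (default 1e18)",
      "packing_fraction": "MNP volume fraction of a settled plug (default 0.01)"
    }
  },
  "derived": {
    "stack.channel_thickness": "equals channel width",
    "stack.eps_channel": "equals fluid rel_permittivity",
    "electrodes.gap": "equals channel width + 2 * wall thickness"
  }
}
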