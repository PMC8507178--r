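{
  "comment": "Hand-derived expectations for fixture_log.csv. The target is toluene (Cc1ccccc1), mode collective, participants A/B/C. Scores are authored values illustrating the leader dynamics, not recomputed similarities. Session segmentation, leader scan, provenance, uniqueness (InChIKey), scaffold classes and time-played sums were derived by hand at authoring time.",
  "max_score": 1000,
  "unique_molecules": 24,
  "scoring_calls": 27,
  "invalid_events": 0,
  "n_participants": 3,
  "time_played_seconds": 280,
  "time_played_by_participant": {"A": 90, "B": 80, "C": 110},
  "scaffold_molecule_ratio": 0.25,
  "n_scaffold_classes": 6,
  "leader_changes": 6,
  "forefront_creators": ["A", "C"],
  "forefront_participation_pct": 66.66666666666667,
  "n_sessions": 10,
  "sessions": {
    "e01": "s0001", "e02": "s0001", "e03": "s0001", "e04": "s0001",
    "e05": "s0002", "e06": "s0002", "e07": "s0002",
    "e08": "s0003",
    "e09": "s0004", "e10": "s0004",
    "e11": "s0002",
    "e12": "s0005", "e13": "s0005",
    "e14": "s0002",
    "e15": "s0004", "e16": "s0004",
    "e17": "s0006", "e18": "s0006",
    "e19": "s0004",
    "e20": "s0007",
    "e21": "s0005",
    "e22": "s0006",
    "e23": "s0007", "e24": "s0007",
    "e25": "s0008",
    "e26": "s0009",
    "e27": "s0010"
  },
  "target_found": true,
  "target_event_id": "e27",
  "target_path_event_ids": ["e09", "e10", "e12", "e13", "e21", "e27"],
  "target_path_creators": ["C", "A"],
  "target_evolution_steps": 3,
  "target_collaboration_pct": 66.66666666666667
}
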