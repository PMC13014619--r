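{"schema_version":"1.0","subject_id":"EX001","stage":"verbal_immediate","session_time":"2024-03-05T14:30:00Z","attempts":[{"cues":["cue1","cue2","cue3","cue4","cue5","cue6","cue7","cue8","cue9","cue10"],"passed":false,"events":[{"t":800,"action":"select","target":1,"correct":true},{"t":1750,"action":"select","target":0,"correct":true},{"t":2450,"action":"select","target":3,"correct":true},{"t":3650,"action":"select","target":2,"correct":false},{"t":4530,"action":"select","target":1,"correct":true},{"t":5550,"action":"select","target":0,"correct":true},{"t":6310,"action":"select","target":2,"correct":true},{"t":7250,"action":"select","target":3,"correct":true},{"t":7940,"action":"select","target":1,"correct":true},{"t":9040,"action":"select","target":0,"correct":true}]}],"app_version":"2.1.0"}
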