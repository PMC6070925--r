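>ScIMA1_synthetic synthetic stand-in scaffold; nine signature residues YVGSLMQDE planted at 158,216,217,218,219,278,279,307,411
GAAGLNVYLYIVYYPAVLQKILEIKSFVVPLGAHRMIVPAGRCEAMNLSKTAESPVNHVH
GGSIQEAGRTNICIGNTRIHDSVCYCEDIESQEAQEIGITLPKVNSYAILLVLRAQFGCG
SRSRGLPGLVANMFYADLSENRNLSNNKSVGAQVLAVYFGSILHNPIHNAIARGMESFER
ECPEIGGVTKLEFFVCLIPMSEHAPPYTWERAGHRVGSLELGPPTTIYRKFDIDEGSGES
PEEYELTTVGKKTEPQTFGRIRKVRKLVAEGYSHDRTMQMSTRKESTIQHVNLGKTLEAV
DGNGGTDQLSGTVESPNGAIFENFRHSTVIGLDEVREKREIKFNAADPQRTKIHTTRTIH
PDDIIALLNYKGVDQDSNAVETLRHMVEIQFLFAASTRGLNKLAPAQQDSEILDDYMVET
ISEHRGLKDDVFLRALECWARGQAYLLKTEIENIEGRQDRHILQDQGLTHSSKASVNPGV
VRCLHRSKMIAGALCAGGIPYGDLGAESRSGSRTYILEAATVTGNTAGDRQFAKVLPPTL
TGTSMENQAAFLPPTFLDVRQLLHLALRGDDRGSLAEQTSLLGQMGSLK
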