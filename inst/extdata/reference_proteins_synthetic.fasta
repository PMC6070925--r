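>AG_ref_synthetic role=AG synthetic alpha-glucosidase reference (identical to the signature scaffold)
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
>AGT_ref_synthetic role=AGT synthetic alpha-glucoside transporter reference
SFERQQGRNNENEGGDSLTQMRKDELVDLRAADIFGMVEQAFSVGPGMDLPTVVKPSSAG
LFMSEFLHVAPSIAASIGMVTIMFLAIRVGFLKARLGGNRVFVAAVCWAYPNDDLTREGG
IDDKTTKNHEEVYFYLGAGQPYPGPKEPRQGAETGNNIQPNKALLLYNGKHFSDRGEPLD
TLMAAWEGDSPSGINTGVTCLQANLNIQLLLYKNANPLKEYPSKVIKLVRQVIPKFEHQD
LKTWNRWSALADPQCMECEIKKHHGQGDQGDALVDIKVQQRDEWDIGVLGGLFEPIGSTN
PAACPGTWEKSLKTEHDDGSAMTGGCSPNVSQKVTNDKYALVEPLGNGGYPGPGSVMDEV
ICALRLKAAKLNVRIYKGKGTTKFKAMANPESEGFHLKTPAQAFMVFASYMHMGKTTKWI
LDKGERVTLGDILYLAAEYEGVNPLADGIYVEFFSRTASETEGRNALDSQTTGQVVMYNI
YNGKIIGANFRVMQMLKRPDRPNAGAHFKGLAIDSLRIASFKTTYWRNVVLPHLLTDFQI
GFKEFSVAVA
>ACT_ref_synthetic role=ACT synthetic Zn(2)-Cys(6) MAL-activator reference
DNANKVQDGPGSSTARDRLNTNDQTTEDLRHPSWETSRDVDDKSLYKEPNSRGTCGEDLE
ICRKVNRLTKLFPEDITRSESLIVVITQHSTVELPHGGYKPMADANTVTMLADPACQFWD
ESSVKLAELGIDVVPQRSSLEPTANEMIEDPAACLDYVKRQPLQQSTAKMAASTAYQSNG
ASAPKFWFQAGIDVGGTGTTLGHVAKPARDQTFRWSMGFKTSCLRTSTSIPMPFNAKGKE
LTNLTPDGEDFQLGSEHIDMETRSLVQALEMLDHTKSDFSQSRERDGPLGEENKLNHLFF
KRLRHLLQSIRAYLPVSNLNFAGTERSRMSQGLEFECSTRAGRYKQEAALLQDSNDFPKG
FQKNYSLLPENKLVCRLLRLDSQCTILNVESDGGNRFLTVPNRREGDKVITPGSVENQPM
EGGLAVNGFAPSQSDEEVSNIQMAYGRDAEPDYPGSAIDGPYELQQPLAA
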