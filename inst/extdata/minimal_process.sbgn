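<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description" id="minimal_process">
    <glyph class="macromolecule" id="ep_a">
      <label text="A"/>
      <bbox x="20" y="40" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_b">
      <label text="B"/>
      <bbox x="220" y="40" w="80" h="40"/>
    </glyph>
    <glyph class="process" id="pr_p">
      <bbox x="140" y="50" w="20" h="20"/>
    </glyph>
    <arc class="consumption" id="a1" source="ep_a" target="pr_p"/>
    <arc class="production" id="a2" source="pr_p" target="ep_b"/>
  </map>
</sbgn>
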